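#' Mean-centre one wave and form its sample moments
#'
#' Restricts to complete cases at the wave (rows with any missing symptom
#' are excluded and counted), mean-centres each symptom column, and returns
#' the centred score matrix together with the Pearson correlation matrix and
#' effective sample size that feed the network estimator.
#'
#' @param panel a `panel_data` object.
#' @param wave wave label (e.g. `"T0"`).
#' @return List with `scores` (centred complete-case matrix), `moments`
#'   (list `S`, `n`, `labels` — a `sample_moments` object) and `n_excluded`.
#' @export
center_within_wave <- function(panel, wave) {
  labs <- attr(panel, "labels")
  m <- wave_scores(panel, wave, labs)
  cc <- stats::complete.cases(m)
  x <- m[cc, , drop = FALSE]
  if (nrow(x) < 10) {
    stopf("wave '%s' has %d complete cases; at least 10 required", wave, nrow(x))
  }
  if (nrow(x) < length(labs) + 1) {
    stopf(
      "wave '%s': %d complete cases are fewer than nodes + 1 (%d); collect more data",
      wave, nrow(x), length(labs) + 1
    )
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stopf("zero-variance symptom column at wave '%s': %s",
          wave, paste(labs[sds == 0], collapse = ", "))
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  list(
    scores = x,
    moments = sample_moments(cor(x), nrow(x), labs),
    n_excluded = sum(!cc)
  )
}

#' Sample moments for network estimation
#'
#' @param S symmetric correlation matrix with unit diagonal.
#' @param n effective sample size.
#' @param labels node labels.
#' @return A `sample_moments` list.
#' @export
sample_moments <- function(S, n, labels = colnames(S)) {
  S <- as.matrix(S)
  stopifnot(isSymmetric(S, tol = 1e-8), all(abs(diag(S) - 1) < 1e-8))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stopf("correlation matrix is not positive semi-definite")
  dimnames(S) <- list(labels, labels)
  structure(list(S = S, n = as.integer(n), labels = labels),
            class = "sample_moments")
}

#' L1-penalized precision-matrix estimation
#'
#' Maximizes `log det K - trace(S K) - lambda * sum(|K_offdiag|)` by block
#' coordinate descent (columnwise lasso sub-problems with warm starts);
#' convergence is declared when the mean absolute change of the working
#' covariance per sweep falls below `tol` relative to the mean absolute
#' off-diagonal of `S`. The diagonal is not penalized. At `lambda = 0` the
#' solution is the matrix inverse of `S`.
#'
#' @param S symmetric positive semi-definite correlation matrix.
#' @param lambda non-negative penalty.
#' @param tol relative convergence tolerance.
#' @param max_iter maximum number of full sweeps.
#' @return The estimated precision matrix `K` with attributes `iterations`
#'   and `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-4, max_iter = 200) {
  stopifnot(lambda >= 0)
  S <- as.matrix(S)
  fit <- glasso_cpp(S, lambda, tol, as.integer(max_iter))
  if (!fit$converged) {
    stopf("graphical lasso did not converge in %d sweeps (last mean change %.3g)",
          max_iter, fit$delta)
  }
  K <- fit$K
  dimnames(K) <- dimnames(S)
  attr(K, "iterations") <- fit$iterations
  attr(K, "converged") <- fit$converged
  K
}

# partial correlations from a precision matrix: w_ij = -K_ij / sqrt(K_ii K_jj)
precision_to_partials <- function(K) {
  d <- sqrt(diag(K))
  W <- -K / tcrossprod(d)
  diag(W) <- 0
  dimnames(W) <- dimnames(K)
  W
}

#' Estimate a partial-correlation network with EBIC model selection
#'
#' Fits the penalized precision matrix along a logarithmic penalty grid from
#' `lambda_max = max |S_offdiag|` down to `lambda_max * lambda_min_ratio`
#' (warm-started), scores each fit by the extended Bayesian information
#' criterion
#' `EBIC = -2 L + E log(n) + 4 gamma E log(P)` with
#' `L = (n/2)(log det K - trace(S K))` and `E` the number of nonzero
#' upper-triangle edges, and returns the fit minimizing the EBIC (ties go to
#' the sparser, more penalized fit).
#'
#' @param moments a [sample_moments()] object.
#' @param gamma EBIC hyperparameter (>= 0); `gamma = 0` reduces to the BIC.
#' @param n_lambda number of grid points (>= 2).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param tol,max_iter passed to the penalized solver.
#' @return A `ggm_fit` object: `K`, partial-correlation matrix `W`,
#'   `lambda_selected`, `ebic_trace` (data frame of lambda, edge count,
#'   log-likelihood, EBIC), `gamma`, `n`, `labels`.
#' @export
ebic_select <- function(moments, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01, tol = 1e-4, max_iter = 200) {
  stopifnot(inherits(moments, "sample_moments"), gamma >= 0, n_lambda >= 2)
  S <- moments$S
  n <- moments$n
  P <- ncol(S)
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max <= 0) lam_max <- 1e-4
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  lambdas[1] <- lam_max  # exactly, so the empty model is on the grid
  path <- glasso_path_cpp(S, lambdas, tol, as.integer(max_iter))
  if (!any(path$converged)) {
    stopf("no penalized fit converged over the %d-point grid", n_lambda)
  }
  ll <- (n / 2) * (path$logdet - path$trace_SK)
  E <- path$n_edges
  ebic <- -2 * ll + E * log(n) + 4 * gamma * E * log(P)
  ebic[!path$converged | !is.finite(path$logdet)] <- Inf
  best <- which.min(ebic)  # first index = largest lambda wins ties
  K <- path$K[, , best]
  dimnames(K) <- dimnames(S)
  structure(
    list(
      K = K,
      W = precision_to_partials(K),
      lambda_selected = lambdas[best],
      ebic_trace = data.frame(
        lambda = lambdas, n_edges = E, loglik = ll, ebic = ebic,
        converged = as.logical(path$converged)
      ),
      gamma = gamma,
      n = n,
      labels = moments$labels
    ),
    class = "ggm_fit"
  )
}

#' @export
print.ggm_fit <- function(x, ...) {
  E <- sum(x$W[upper.tri(x$W)] != 0)
  total <- sum(upper.tri(x$W))
  cat(sprintf(
    "ggm_fit: %d nodes, %d/%d edges (%.1f%%), lambda = %.4g (gamma = %.2g, n = %d)\n",
    length(x$labels), E, total, 100 * E / total, x$lambda_selected, x$gamma, x$n
  ))
  w <- x$W[upper.tri(x$W)]
  if (any(w != 0)) {
    idx <- which(upper.tri(x$W), arr.ind = TRUE)
    ord <- order(abs(w), decreasing = TRUE)[seq_len(min(3, sum(w != 0)))]
    for (k in ord) {
      cat(sprintf("  %s--%s: %.3f\n",
                  x$labels[idx[k, 1]], x$labels[idx[k, 2]], w[k]))
    }
  }
  invisible(x)
}

#' Estimate one wave's network from a panel
#'
#' Convenience wrapper: [center_within_wave()] then [ebic_select()].
#'
#' @param panel a `panel_data` object.
#' @param wave wave label.
#' @param ... passed to [ebic_select()].
#' @return A `ggm_fit` object.
#' @export
fit_wave_ggm <- function(panel, wave, ...) {
  ebic_select(center_within_wave(panel, wave)$moments, ...)
}
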