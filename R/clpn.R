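#' Assemble the lagged regression design for one outcome
#'
#' Rows are participants with complete symptom data at both waves and
#' complete covariates (listwise over the wave pair, so all nine outcome
#' regressions share one sample). Predictors are the nine lagged symptom
#' scores plus the four covariates; lagged scores and the outcome are
#' mean-centred within the design sample.
#'
#' @param panel a `panel_data` object.
#' @param from_wave,to_wave wave labels, `from_wave` preceding `to_wave`.
#' @param outcome symptom label of the outcome at `to_wave`.
#' @return A `lagged_design`: list with `X` (n x 13 predictor matrix),
#'   `y`, `outcome_label`, `n_complete`, `predictor_labels`,
#'   `penalized` (logical per predictor), `participant_id`, `wave_pair`.
#' @export
build_lagged_design <- function(panel, from_wave, to_wave, outcome) {
  labs <- attr(panel, "labels")
  covs <- attr(panel, "covariates")
  if (!outcome %in% labs) stopf("unknown outcome label '%s'", outcome)

  a <- panel[panel$wave == from_wave, , drop = FALSE]
  b <- panel[panel$wave == to_wave, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stopf("waves '%s'/'%s' not both present", from_wave, to_wave)
  ids <- intersect(a$participant_id, b$participant_id)
  a <- a[match(ids, a$participant_id), , drop = FALSE]
  b <- b[match(ids, b$participant_id), , drop = FALSE]

  ok <- stats::complete.cases(a[, labs, drop = FALSE]) &
    stats::complete.cases(b[, labs, drop = FALSE]) &
    stats::complete.cases(a[, covs, drop = FALSE])
  n_complete <- sum(ok)
  if (n_complete < length(labs) + length(covs) + 1) {
    stopf("only %d complete two-wave cases; at least %d required",
          n_complete, length(labs) + length(covs) + 1)
  }

  Xlag <- scale(as.matrix(a[ok, labs, drop = FALSE]), center = TRUE, scale = FALSE)
  attr(Xlag, "scaled:center") <- NULL
  Xcov <- as.matrix(a[ok, covs, drop = FALSE])
  y <- as.numeric(scale(b[ok, outcome, drop = TRUE], center = TRUE, scale = FALSE))

  ord <- order(a$participant_id[ok])
  X <- cbind(Xlag, Xcov)[ord, , drop = FALSE]
  structure(
    list(
      X = X,
      y = y[ord],
      outcome_label = outcome,
      n_complete = n_complete,
      predictor_labels = c(labs, covs),
      penalized = c(rep(TRUE, length(labs)), rep(FALSE, length(covs))),
      participant_id = a$participant_id[ok][ord],
      wave_pair = c(from_wave, to_wave)
    ),
    class = "lagged_design"
  )
}

#' Cross-validated LASSO for one outcome regression
#'
#' Coordinate-descent LASSO (via glmnet) over a decreasing penalty grid,
#' with ten-fold cross-validation on the Gaussian deviance. The penalty is
#' selected by the one-standard-error rule: the largest grid value whose
#' mean CV deviance is within one standard error of the minimum
#' (`lambda.1se >= lambda.min` by construction). Predictors are
#' standardized internally for the penalty and coefficients returned on the
#' centred-score scale. Covariate columns (`penalized = FALSE` in the
#' design) carry zero penalty and are always retained.
#'
#' If a CV fold happens to have zero outcome variance the folds are
#' reshuffled with the next derived seed (logged via `message`).
#'
#' @param design a [build_lagged_design()] object.
#' @param n_folds number of CV folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @param n_lambda grid length.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @return A `lasso_path`: `lambda_grid`, `cv_mean`, `cv_se`,
#'   `lambda_min`, `lambda_1se`, `coef_1se`, `coef_min` (named, without
#'   intercept), `intercept`, `n_folds`, `seed`.
#' @export
cv_lasso <- function(design, n_folds = 10, seed = 1L, n_lambda = 100,
                     lambda_min_ratio = 0.001) {
  stopifnot(inherits(design, "lagged_design"), n_folds >= 2)
  n <- length(design$y)
  if (n < n_folds) stopf("n_complete (%d) below the number of folds (%d)", n, n_folds)

  foldid <- NULL
  for (try in 0:9) {
    foldid <- with_seed(derive_seed(seed, try), sample(rep_len(seq_len(n_folds), n)))
    ok <- all(vapply(seq_len(n_folds),
                     function(f) stats::var(design$y[foldid == f]) > 0,
                     logical(1)))
    if (ok) break
    message(sprintf("cv_lasso(%s): fold with zero outcome variance; reshuffling",
                    design$outcome_label))
  }

  fit <- glmnet::cv.glmnet(
    design$X, design$y,
    family = "gaussian", type.measure = "deviance",
    nlambda = n_lambda, lambda.min.ratio = lambda_min_ratio,
    penalty.factor = as.numeric(design$penalized),
    standardize = TRUE, foldid = foldid
  )
  co_1se <- as.numeric(coef(fit, s = "lambda.1se"))
  co_min <- as.numeric(coef(fit, s = "lambda.min"))
  nm <- c("(Intercept)", design$predictor_labels)
  structure(
    list(
      lambda_grid = fit$lambda,
      cv_mean = fit$cvm,
      cv_se = fit$cvsd,
      lambda_min = fit$lambda.min,
      lambda_1se = fit$lambda.1se,
      intercept = co_1se[1],
      coef_1se = setNames(co_1se[-1], nm[-1]),
      coef_min = setNames(co_min[-1], nm[-1]),
      outcome_label = design$outcome_label,
      n = n, n_folds = n_folds, seed = seed
    ),
    class = "lasso_path"
  )
}

#' Fit a cross-lagged panel network for a wave pair
#'
#' Runs one penalized regression per symptom (nine node-wise LASSO fits
#' with ten-fold CV and one-standard-error penalty selection, covariates
#' unpenalized) and assembles the 9 x 9 lagged coefficient matrix `A`:
#' autoregressive effects on the diagonal, cross-lagged effects
#' off-diagonal, with `A[i, j]` the effect of symptom `i` at the earlier
#' wave on symptom `j` at the later wave. Per-outcome fold seeds are
#' derived from the master seed by outcome index, and fold assignment is
#' keyed to sorted participant IDs, so the fit is reproducible and
#' invariant to input row order.
#'
#' @param panel a `panel_data` object.
#' @param from_wave,to_wave ordered wave labels.
#' @param seed master integer seed.
#' @param n_folds CV folds per outcome regression.
#' @param ... passed to [cv_lasso()].
#' @return A `clpn_fit`: `A`, `covariate_coefs` (4 x 9), `wave_pair`,
#'   `n_complete`, `paths` (per-outcome `lasso_path` list),
#'   `nonzero_1se`/`nonzero_min` counts, `seed`, `labels`.
#' @export
fit_clpn <- function(panel, from_wave, to_wave, seed = 1L, n_folds = 10, ...) {
  labs <- attr(panel, "labels")
  covs <- attr(panel, "covariates")
  p <- length(labs)
  A <- matrix(0, p, p, dimnames = list(labs, labs))
  Cc <- matrix(0, length(covs), p, dimnames = list(covs, labs))
  paths <- vector("list", p)
  names(paths) <- labs
  n_complete <- NA_integer_
  nz_1se <- nz_min <- 0L
  for (j in seq_len(p)) {
    design <- build_lagged_design(panel, from_wave, to_wave, labs[j])
    n_complete <- design$n_complete
    path <- tryCatch(
      cv_lasso(design, n_folds = n_folds, seed = derive_seed(seed, j), ...),
      error = function(e) stopf("outcome %s: %s", labs[j], conditionMessage(e))
    )
    A[, j] <- path$coef_1se[labs]
    Cc[, j] <- path$coef_1se[covs]
    nz_1se <- nz_1se + sum(path$coef_1se[labs] != 0)
    nz_min <- nz_min + sum(path$coef_min[labs] != 0)
    paths[[j]] <- path
  }
  structure(
    list(
      A = A, covariate_coefs = Cc, wave_pair = c(from_wave, to_wave),
      n_complete = n_complete, paths = paths,
      nonzero_1se = nz_1se, nonzero_min = nz_min,
      seed = seed, labels = labs
    ),
    class = "clpn_fit"
  )
}

#' @export
print.clpn_fit <- function(x, ...) {
  off <- x$A[row(x$A) != col(x$A)]
  cat(sprintf(
    "clpn_fit %s -> %s: n = %d, %d/%d nonzero cross-lagged paths\n",
    x$wave_pair[1], x$wave_pair[2], x$n_complete, sum(off != 0), length(off)
  ))
  if (any(off != 0)) {
    idx <- which(row(x$A) != col(x$A), arr.ind = TRUE)
    vals <- x$A[idx]
    ord <- order(abs(vals), decreasing = TRUE)[seq_len(min(3, sum(vals != 0)))]
    for (k in ord) {
      cat(sprintf("  %s -> %s: B = %.3f\n",
                  x$labels[idx[k, 1]], x$labels[idx[k, 2]], vals[k]))
    }
  }
  invisible(x)
}

#' Directed expected-influence centrality
#'
#' In-expected influence (sum of incoming cross-lagged weights, column sums
#' of `A` excluding the autoregressive diagonal) and out-expected influence
#' (outgoing, row sums excluding the diagonal), each also z-scored across
#' the nine nodes within the network.
#'
#' @param net a `clpn_fit` or a square directed coefficient matrix.
#' @return A `directed_centrality` data frame: `node`, `in_ei`,
#'   `out_ei`, `in_ei_z`, `out_ei_z`.
#' @export
directed_expected_influence <- function(net) {
  A <- if (inherits(net, "clpn_fit")) net$A else as.matrix(net)
  stopifnot(nrow(A) == ncol(A), all(is.finite(A)))
  off <- A
  diag(off) <- 0
  in_ei <- colSums(off)
  out_ei <- rowSums(off)
  out <- data.frame(
    node = rownames(A),
    in_ei = unname(in_ei), out_ei = unname(out_ei),
    in_ei_z = unname(zscore(in_ei)), out_ei_z = unname(zscore(out_ei))
  )
  class(out) <- c("directed_centrality", "data.frame")
  out
}
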