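#' Built-in bootstrap estimators
#'
#' Estimator closures for [bootstrap_estimates()] and
#' [case_dropping_cs()]. Each takes a case-level dataset and returns a list
#' with `edges` (named numeric vector) and `centrality` (named index ->
#' per-node vector list).
#'
#' `ggm_boot_estimator` consumes a score matrix (rows = participants):
#' correlations are recomputed, the network re-selected by EBIC, and the
#' four cross-sectional indices recomputed. `clpn_boot_estimator` consumes
#' a `panel_data` and refits the cross-lagged network for the given wave
#' pair, returning the 81 directed coefficients and in-/out-expected
#' influence.
#'
#' @param gamma EBIC hyperparameter for the network fit.
#' @param from_wave,to_wave wave pair for the lagged network.
#' @param seed seed forwarded to the lagged fit (fold assignment).
#' @param ... passed on to [ebic_select()] / [fit_clpn()].
#' @return A function of one dataset argument.
#' @export
ggm_boot_estimator <- function(gamma = 0.5, ...) {
  force(gamma)
  dots <- list(...)
  function(x) {
    x <- as.matrix(x)
    fit <- do.call(ebic_select, c(
      list(sample_moments(cor(x), nrow(x), colnames(x)), gamma = gamma), dots
    ))
    W <- fit$W
    idx <- which(upper.tri(W), arr.ind = TRUE)
    edges <- setNames(
      W[upper.tri(W)],
      paste(fit$labels[idx[, 1]], fit$labels[idx[, 2]], sep = "--")
    )
    cen <- centrality_table(W)
    centrality <- lapply(split(cen, cen$index), function(d) setNames(d$raw, d$node))
    list(edges = edges, centrality = centrality)
  }
}

#' @rdname ggm_boot_estimator
#' @export
clpn_boot_estimator <- function(from_wave, to_wave, seed = 1L, ...) {
  force(from_wave); force(to_wave); force(seed)
  dots <- list(...)
  function(panel) {
    fit <- do.call(fit_clpn, c(list(panel, from_wave, to_wave, seed = seed), dots))
    A <- fit$A
    idx <- which(matrix(TRUE, nrow(A), ncol(A)), arr.ind = TRUE)
    edges <- setNames(A[idx], paste(fit$labels[idx[, 1]], fit$labels[idx[, 2]], sep = "->"))
    dc <- directed_expected_influence(fit)
    list(
      edges = edges,
      centrality = list(
        in_expected_influence = setNames(dc$in_ei, dc$node),
        out_expected_influence = setNames(dc$out_ei, dc$node)
      )
    )
  }
}

resample_cases <- function(data, idx) {
  if (inherits(data, "panel_data")) {
    ids <- unique(data$participant_id)
    take <- ids[idx]
    pieces <- lapply(seq_along(take), function(k) {
      sub <- data[data$participant_id == take[k], , drop = FALSE]
      sub$participant_id <- sprintf("B%06d", k)
      sub
    })
    as_panel_data(do.call(rbind, pieces),
                  labels = attr(data, "labels"),
                  covariates = attr(data, "covariates"))
  } else {
    data[idx, , drop = FALSE]
  }
}

n_cases <- function(data) {
  if (inherits(data, "panel_data")) length(unique(data$participant_id)) else nrow(data)
}

#' Nonparametric bootstrap of network estimates
#'
#' Draws `B` n-out-of-n resamples of cases (participants) with
#' replacement, re-runs the estimator on each, and stores every edge and
#' centrality replicate. Replicates whose estimation fails are dropped and
#' counted; more than 5% failures triggers a warning.
#'
#' @param data score matrix (rows = cases) or `panel_data`.
#' @param estimator a function as built by [ggm_boot_estimator()] /
#'   [clpn_boot_estimator()].
#' @param B number of bootstrap samples.
#' @param seed integer seed for the resampling stream.
#' @return A `bootstrap_distribution`: `edges` (B x n_edges matrix),
#'   `centrality` (index -> B x n_nodes matrix list), `observed` (full-
#'   sample estimate), `B`, `n_failed`, `seed`.
#' @export
bootstrap_estimates <- function(data, estimator, B = 1000, seed = 1L) {
  n <- n_cases(data)
  observed <- estimator(data)
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(estimator(resample_cases(data, idx)), error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed estimation", n_failed, B))
  }
  reps <- reps[ok]
  edges <- do.call(rbind, lapply(reps, `[[`, "edges"))
  centrality <- lapply(names(observed$centrality), function(ix) {
    do.call(rbind, lapply(reps, function(r) r$centrality[[ix]]))
  })
  names(centrality) <- names(observed$centrality)
  structure(
    list(edges = edges, centrality = centrality, observed = observed,
         B = B, n_kept = sum(ok), n_failed = n_failed, seed = seed),
    class = "bootstrap_distribution"
  )
}

#' Percentile bootstrap confidence intervals for edges
#'
#' @param dist a [bootstrap_estimates()] result.
#' @param level confidence level in (0, 1).
#' @return Data frame `edge`, `estimate`, `lower`, `upper`.
#' @export
edge_ci <- function(dist, level = 0.95) {
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  qs <- apply(dist$edges, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(
    edge = colnames(dist$edges),
    estimate = unname(dist$observed$edges[colnames(dist$edges)]),
    lower = qs[1, ], upper = qs[2, ],
    row.names = NULL
  )
}

#' Bootstrap difference tests
#'
#' For every pair of edges (or of nodes within a centrality index) the
#' bootstrap distribution of their difference is formed; a pair differs
#' significantly iff the percentile interval of the difference excludes
#' zero. The result is a symmetric logical matrix with a `FALSE` diagonal.
#'
#' @param dist a [bootstrap_estimates()] result.
#' @param what `"edges"` or a centrality index name stored in `dist`.
#' @param level confidence level.
#' @return Symmetric logical matrix of significant differences.
#' @export
difference_tests <- function(dist, what = "edges", level = 0.95) {
  M <- if (identical(what, "edges")) dist$edges else dist$centrality[[what]]
  if (is.null(M)) stopf("no replicates stored for '%s'", what)
  a <- (1 - level) / 2
  k <- ncol(M)
  out <- matrix(FALSE, k, k, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(k - 1)) {
    d <- M[, (i + 1):k, drop = FALSE] - M[, i]
    lo <- apply(d, 2, quantile, probs = a, names = FALSE)
    hi <- apply(d, 2, quantile, probs = 1 - a, names = FALSE)
    sig <- lo > 0 | hi < 0
    out[i, (i + 1):k] <- sig
    out[(i + 1):k, i] <- sig
  }
  out
}

# correlation used for the CS criterion; identical vectors count as 1 even
# when constant (a constant estimator is perfectly stable by convention)
cs_correlation <- function(a, b, method = "pearson") {
  if (isTRUE(all.equal(unname(a), unname(b)))) return(1)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b, method = method)
}

#' Case-dropping stability and the CS coefficient
#'
#' For each drop proportion `p` in the grid, draws subsamples of size
#' `round((1 - p) n)` without replacement, re-estimates the network, and
#' correlates each centrality index with its full-sample value across
#' nodes. `prob_ge_070` is the fraction of subsamples correlating at least
#' 0.70; the CS coefficient is the largest tested proportion at which that
#' fraction is at least 0.95 (0 if none). Interpretation bands: > 0.50
#' excellent, 0.25-0.50 moderate, < 0.25 insufficient.
#'
#' @param data score matrix or `panel_data`.
#' @param estimator as in [bootstrap_estimates()].
#' @param drop_grid ascending drop proportions in (0, 1).
#' @param n_subsamples subsamples per proportion (>= 50 for reporting).
#' @param seed integer seed.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return A `cs_report`: per-index `cs_coefficient` and band, the
#'   `prob_ge_070` curves, and the raw subsample correlations.
#' @export
case_dropping_cs <- function(data, estimator, drop_grid = seq(0.05, 0.75, by = 0.05),
                             n_subsamples = 100, seed = 1L,
                             cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  stopifnot(all(drop_grid > 0), all(drop_grid < 1), !is.unsorted(drop_grid))
  n <- n_cases(data)
  full <- estimator(data)$centrality
  indices <- names(full)

  cors <- with_seed(seed, {
    lapply(drop_grid, function(p) {
      size <- round((1 - p) * n)
      m <- vapply(seq_len(n_subsamples), function(s) {
        idx <- sample.int(n, size, replace = FALSE)
        est <- tryCatch(estimator(resample_cases(data, idx)), error = function(e) NULL)
        # NaN marks an estimation failure (infeasible subsample); NA marks an
        # undefined correlation (constant vector), which counts against 0.70
        if (is.null(est)) return(rep(NaN, length(indices)))
        vapply(indices, function(ix) {
          cs_correlation(est$centrality[[ix]][names(full[[ix]])], full[[ix]],
                         method = cor_method)
        }, numeric(1))
      }, numeric(length(indices)))
      matrix(m, nrow = length(indices), dimnames = list(indices, NULL))
    })
  })

  feasible <- vapply(cors, function(m) mean(colSums(is.nan(m)) > 0) <= 0.5, logical(1))
  prob <- sapply(seq_along(drop_grid), function(k) {
    m <- cors[[k]]
    vapply(seq_along(indices), function(i) {
      v <- m[i, ]
      if (!feasible[k]) return(NA_real_)
      mean(!is.na(v) & v >= 0.70)
    }, numeric(1))
  })
  prob <- matrix(prob, nrow = length(indices),
                 dimnames = list(indices, sprintf("%.2f", drop_grid)))

  cs <- vapply(indices, function(ix) {
    hits <- which(feasible & prob[ix, ] >= 0.95)
    if (length(hits)) drop_grid[max(hits)] else 0
  }, numeric(1))
  band <- ifelse(cs > 0.50, "excellent",
                 ifelse(cs >= 0.25, "moderate", "insufficient"))

  structure(
    list(
      cs_coefficient = cs,
      band = setNames(band, indices),
      drop_grid = drop_grid,
      feasible = feasible,
      prob_ge_070 = prob,
      correlations = cors,
      n_subsamples = n_subsamples,
      cor_method = cor_method,
      seed = seed
    ),
    class = "cs_report"
  )
}

#' @export
print.cs_report <- function(x, ...) {
  cat(sprintf("case-dropping stability (%d subsamples/level, %s correlation)\n",
              x$n_subsamples, x$cor_method))
  for (ix in names(x$cs_coefficient)) {
    cat(sprintf("  CS(%s) = %.2f [%s]\n", ix, x$cs_coefficient[ix], x$band[ix]))
  }
  invisible(x)
}
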