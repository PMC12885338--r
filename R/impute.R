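#' Multiple imputation by chained equations with predictive mean matching
#'
#' Imputes missing symptom cells in a wide participant layout (all waves'
#' symptom columns jointly, plus covariates, so cross-wave dependence is
#' preserved). Each incomplete column is iteratively regressed on all other
#' columns; missing entries receive the observed value of one of the
#' `donors` cases whose predicted values are nearest to the predicted value
#' of the missing case (predictive mean matching, which keeps imputed
#' values inside the observed range). The `m` completed datasets come from
#' independent seeded streams. Observed cells are never altered.
#'
#' @param panel a `panel_data` object; missingness must be confined to the
#'   symptom columns (covariates complete).
#' @param m number of completed datasets.
#' @param seed integer master seed.
#' @param max_iter chained-equation iterations per dataset.
#' @param donors donor-pool size for predictive mean matching.
#' @return An `imputation_set`: list with `m`, `datasets` (completed
#'   `panel_data` objects), `method`, `seed`.
#' @export
impute_chained <- function(panel, m = 20, seed = 1L, max_iter = 10, donors = 5) {
  labs <- attr(panel, "labels")
  covs <- attr(panel, "covariates")
  waves <- attr(panel, "waves")
  if (anyNA(panel[, covs])) stopf("covariates must be complete for imputation")

  # wide layout: one row per participant, symptom columns per wave
  ids <- sort(unique(panel$participant_id))
  wide <- matrix(NA_real_, length(ids), length(labs) * length(waves) + length(covs))
  wcols <- c(
    as.vector(outer(labs, waves, function(l, w) paste(l, w, sep = "."))),
    covs
  )
  dimnames(wide) <- list(ids, wcols)
  for (w in waves) {
    sub <- panel[panel$wave == w, , drop = FALSE]
    wide[match(sub$participant_id, ids), paste(labs, w, sep = ".")] <-
      as.matrix(sub[, labs, drop = FALSE])
  }
  first <- panel[match(ids, panel$participant_id), covs, drop = FALSE]
  wide[, covs] <- as.matrix(first)

  frac_missing <- colMeans(is.na(wide))
  if (any(frac_missing > 0.8)) {
    stopf("column(s) with > 80%% missingness cannot be imputed reliably: %s",
          paste(names(which(frac_missing > 0.8)), collapse = ", "))
  }
  incomplete <- names(which(frac_missing > 0))

  impute_once <- function(sub_seed) {
    with_seed(sub_seed, {
      x <- wide
      miss <- is.na(wide)
      # initial fill: random draws from each column's observed values
      for (col in incomplete) {
        obs <- x[!miss[, col], col]
        x[miss[, col], col] <- sample(obs, sum(miss[, col]), replace = TRUE)
      }
      if (!length(incomplete)) return(x)
      for (it in seq_len(max_iter)) {
        for (col in incomplete) {
          others <- setdiff(colnames(x), col)
          X <- cbind(1, x[, others, drop = FALSE])
          obs_rows <- which(!miss[, col])
          mis_rows <- which(miss[, col])
          fit <- stats::lm.fit(X[obs_rows, , drop = FALSE], x[obs_rows, col])
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          pred <- as.numeric(X %*% beta)
          for (r in mis_rows) {
            pool <- order(abs(pred[obs_rows] - pred[r]))[seq_len(min(donors, length(obs_rows)))]
            donor <- obs_rows[pool[sample.int(length(pool), 1)]]
            x[r, col] <- x[donor, col]
          }
        }
      }
      x
    })
  }

  datasets <- lapply(seq_len(m), function(k) {
    x <- impute_once(derive_seed(seed, k))
    out <- as.data.frame(panel)
    for (w in waves) {
      rows <- out$wave == w
      out[rows, labs] <- x[match(out$participant_id[rows], ids),
                           paste(labs, w, sep = ".")]
    }
    as_panel_data(out, labels = labs, covariates = covs)
  })

  structure(
    list(m = m, datasets = datasets,
         method = sprintf("chained PMM (donors = %d, %d iterations)", donors, max_iter),
         n_incomplete_columns = length(incomplete), seed = seed),
    class = "imputation_set"
  )
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: m = %d completed datasets, %s, %d incomplete columns\n",
              x$m, x$method, x$n_incomplete_columns))
  invisible(x)
}

#' Pooled re-analysis of an imputation set
#'
#' Runs [analyze_networks()] on each completed dataset and pools across
#' the `m` datasets. Two pooling modes are offered for the cross-sectional
#' networks:
#'
#' * `"estimates"` (default): entrywise mean of the estimated edge
#'   matrices (the point-estimate part of Rubin's rules). The pooled
#'   matrix is generally dense, because an edge selected in any one
#'   completed dataset contributes.
#' * `"moments"`: mean of the per-dataset correlation matrices followed by
#'   a single EBIC-selected fit on the pooled moments (the "re-analyse the
#'   pooled data" reading). The pooled network is sparse like an ordinary
#'   single-dataset fit, which keeps its zero pattern comparable with
#'   complete-case fits in rank-agreement analyses.
#'
#' Lagged coefficient matrices are pooled by entrywise mean in both modes.
#' Centralities are recomputed from the pooled matrices.
#'
#' @param imp an [impute_chained()] result.
#' @param gamma,seed,... passed to [analyze_networks()].
#' @param mode pooling mode for the cross-sectional networks, see above.
#' @return A `network_analysis` whose `W` and `A` are pooled (the
#'   `ggm`/`clpn` per-dataset fit lists are omitted).
#' @export
pooled_networks <- function(imp, gamma = 0.5, seed = 1L,
                            mode = c("estimates", "moments"), ...) {
  stopifnot(inherits(imp, "imputation_set"))
  mode <- match.arg(mode)
  fits <- lapply(imp$datasets, analyze_networks, gamma = gamma, seed = seed, ...)
  waves <- fits[[1]]$waves
  has_clpn <- length(fits[[1]]$A) > 0
  pool_mats <- function(get) {
    keys <- names(get(fits[[1]]))
    out <- lapply(keys, function(k) {
      Reduce(`+`, lapply(fits, function(f) get(f)[[k]])) / length(fits)
    })
    names(out) <- keys
    out
  }
  if (mode == "estimates") {
    W <- pool_mats(function(f) f$W)
  } else {
    W <- lapply(waves, function(w) {
      moms <- lapply(imp$datasets, function(d) center_within_wave(d, w)$moments)
      S_pool <- Reduce(`+`, lapply(moms, `[[`, "S")) / length(moms)
      ebic_select(
        sample_moments(S_pool, moms[[1]]$n, moms[[1]]$labels),
        gamma = gamma
      )$W
    })
    names(W) <- waves
  }
  A <- if (has_clpn) pool_mats(function(f) f$A) else list()
  structure(
    list(
      waves = waves,
      W = W,
      centrality = lapply(W, centrality_table),
      ggm = NULL,
      A = A,
      clpn = NULL,
      dcentrality = lapply(A, directed_expected_influence),
      n_per_wave = fits[[1]]$n_per_wave,
      gamma = gamma, seed = seed, m = imp$m, pooling = mode
    ),
    class = "network_analysis"
  )
}

safe_spearman <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b, method = "spearman")
}

#' Spearman agreement between two analyses
#'
#' Rank-correlates an original (e.g. complete-case) analysis with a pooled
#' imputed one: per wave, each centrality index over the nine nodes and the
#' 36 upper-triangle edge weights; per wave pair, the 81 directed
#' coefficients and the in-/out-expected-influence vectors. Constant
#' vectors yield `NA` (correlation undefined).
#'
#' @param original,pooled `network_analysis` objects with matching waves.
#' @return A `sensitivity_report` data frame: `comparison`, `wave`,
#'   `spearman`.
#' @export
compare_spearman <- function(original, pooled) {
  stopifnot(identical(original$waves, pooled$waves))
  rows <- list()
  add <- function(comparison, wave, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, wave = wave, spearman = value
    )
  }
  for (w in original$waves) {
    co <- original$centrality[[w]]
    cp <- pooled$centrality[[w]]
    for (ix in unique(co$index)) {
      a <- co$raw[co$index == ix]
      b <- cp$raw[cp$index == ix][match(co$node[co$index == ix],
                                        cp$node[cp$index == ix])]
      add(paste0("centrality_", ix), w, safe_spearman(a, b))
    }
    add("edge_weights", w,
        safe_spearman(upper_tri_values(original$W[[w]]),
                      upper_tri_values(pooled$W[[w]])))
  }
  for (pair in names(original$A)) {
    add("cross_lagged_paths", pair,
        safe_spearman(as.vector(original$A[[pair]]), as.vector(pooled$A[[pair]])))
    do_ <- original$dcentrality[[pair]]
    dp <- pooled$dcentrality[[pair]]
    add("in_expected_influence", pair, safe_spearman(do_$in_ei, dp$in_ei))
    add("out_expected_influence", pair, safe_spearman(do_$out_ei, dp$out_ei))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_report", "data.frame")
  out
}
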