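#' Core network analysis of a panel
#'
#' Fits the per-wave partial-correlation networks (EBIC selection) with
#' their centrality tables and, for each consecutive wave pair, the
#' cross-lagged network with directed expected-influence centrality. This
#' is the unit re-run on every multiply-imputed dataset and by the full
#' pipeline.
#'
#' @param panel a `panel_data` object.
#' @param gamma EBIC hyperparameter.
#' @param seed master seed (drives the lagged fits' fold assignment).
#' @param waves wave labels to analyse (default: all present).
#' @param clpn fit the cross-lagged networks for consecutive wave pairs
#'   (default `TRUE`; set `FALSE` for a cross-sectional-only analysis).
#' @param ... passed to [ebic_select()].
#' @return A `network_analysis`: named lists `W` (per-wave
#'   partial-correlation matrices), `centrality` (per-wave
#'   [centrality_table()]s), `ggm` (full `ggm_fit`s), `A` (per-pair lagged
#'   coefficient matrices), `clpn` (full `clpn_fit`s), `dcentrality`
#'   (per-pair [directed_expected_influence()] tables), plus `n_per_wave`.
#' @export
analyze_networks <- function(panel, gamma = 0.5, seed = 1L,
                             waves = attr(panel, "waves"), clpn = TRUE, ...) {
  ggm <- list()
  W <- list()
  centrality <- list()
  n_per_wave <- integer(0)
  for (w in waves) {
    cw <- center_within_wave(panel, w)
    fit <- ebic_select(cw$moments, gamma = gamma, ...)
    ggm[[w]] <- fit
    W[[w]] <- fit$W
    centrality[[w]] <- centrality_table(fit$W)
    n_per_wave[w] <- cw$moments$n
  }

  clpn_fits <- list()
  A <- list()
  dcentrality <- list()
  if (isTRUE(clpn) && length(waves) >= 2) {
    for (k in seq_len(length(waves) - 1)) {
      pair <- paste(waves[k], waves[k + 1], sep = "->")
      fit <- fit_clpn(panel, waves[k], waves[k + 1],
                      seed = derive_seed(seed, 100 + k))
      clpn_fits[[pair]] <- fit
      A[[pair]] <- fit$A
      dcentrality[[pair]] <- directed_expected_influence(fit)
    }
  }

  structure(
    list(
      waves = waves, W = W, centrality = centrality, ggm = ggm,
      A = A, clpn = clpn_fits, dcentrality = dcentrality,
      n_per_wave = n_per_wave, gamma = gamma, seed = seed
    ),
    class = "network_analysis"
  )
}

#' @export
print.network_analysis <- function(x, ...) {
  cat(sprintf("network_analysis: %d waves (%s)\n",
              length(x$waves), paste(x$waves, collapse = ", ")))
  for (w in x$waves) {
    E <- sum(x$W[[w]][upper.tri(x$W[[w]])] != 0)
    cat(sprintf("  %s: n = %d, %d edges\n", w, x$n_per_wave[w], E))
  }
  for (pair in names(x$A)) {
    off <- x$A[[pair]][row(x$A[[pair]]) != col(x$A[[pair]])]
    cat(sprintf("  %s: %d nonzero cross-lagged paths\n", pair, sum(off != 0)))
  }
  invisible(x)
}
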