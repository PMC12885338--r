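#' Permutation invariance tests between two networks
#'
#' Compares the partial-correlation networks of two groups with two
#' permutation statistics: the network-structure statistic
#' `M = max_ij |w_ij^A - w_ij^B|` and the global-strength statistic
#' `S = | sum |w^A| - sum |w^B| |` (sums over the upper triangle). Under
#' the null of exchangeable rows, participants are pooled and reassigned to
#' groups of the original sizes; both networks are re-estimated per
#' permutation with the same EBIC selection as the observed fits. P-values
#' use the add-one estimator `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' The two groups are treated as independent; when the groups are waves of
#' the same cohort this ignores the participant overlap, which the result
#' object flags.
#'
#' @param data_a,data_b centred score matrices with identical columns.
#' @param n_permutations permutation count.
#' @param gamma EBIC hyperparameter used for every fit.
#' @param seed integer seed for the permutation stream.
#' @param ... further arguments passed to [ebic_select()].
#' @return An `nct_result`: observed statistics, `p_structure`,
#'   `p_global`, permutation draws, seed and a dependence caveat flag.
#' @export
nct <- function(data_a, data_b, n_permutations = 1000, gamma = 0.5,
                seed = 1L, ...) {
  data_a <- as.matrix(data_a)
  data_b <- as.matrix(data_b)
  if (!identical(colnames(data_a), colnames(data_b))) {
    stopf("groups must share the same symptom columns")
  }
  p <- ncol(data_a)
  na <- nrow(data_a)
  nb <- nrow(data_b)
  if (min(na, nb) < p + 1) {
    stopf("group size %d below nodes + 1 (%d)", min(na, nb), p + 1)
  }

  fit_w <- function(x) {
    ebic_select(sample_moments(cor(x), nrow(x), colnames(x)),
                gamma = gamma, ...)$W
  }
  stats_of <- function(wa, wb) {
    c(
      M = max(abs(wa - wb)),
      S = abs(sum(abs(upper_tri_values(wa))) - sum(abs(upper_tri_values(wb))))
    )
  }

  wa <- fit_w(data_a)
  wb <- fit_w(data_b)
  obs <- stats_of(wa, wb)

  pooled <- rbind(data_a, data_b)
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(i) {
      ia <- sample.int(na + nb, na)
      stats_of(fit_w(pooled[ia, , drop = FALSE]),
               fit_w(pooled[-ia, , drop = FALSE]))
    }, numeric(2)))
  })

  structure(
    list(
      M_observed = unname(obs["M"]),
      S_observed = unname(obs["S"]),
      p_structure = (1 + sum(perm[, "M"] >= obs["M"])) / (1 + n_permutations),
      p_global = (1 + sum(perm[, "S"] >= obs["S"])) / (1 + n_permutations),
      n_permutations = n_permutations,
      perm_M = perm[, "M"],
      perm_S = perm[, "S"],
      gamma = gamma,
      seed = seed,
      n_a = na, n_b = nb,
      independent_groups_assumed = TRUE
    ),
    class = "nct_result"
  )
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "network comparison (%d permutations, n = %d vs %d)\n",
      "  structure: M = %.4f, p = %.4f\n",
      "  global strength: S = %.4f, p = %.4f\n"
    ),
    x$n_permutations, x$n_a, x$n_b,
    x$M_observed, x$p_structure, x$S_observed, x$p_global
  ))
  if (isTRUE(x$independent_groups_assumed)) {
    cat("  note: groups permuted as independent samples; overlapping\n",
        "  participants across waves are not accounted for\n", sep = "")
  }
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m family size (>= length of `p_values`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stopf("family size m smaller than the number of p-values")
  pmin(1, m * p_values)
}
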