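#' Simulate a multi-wave symptom panel from a known structure
#'
#' Draws baseline scores from the zero-mean multivariate normal implied by
#' the ground-truth residual precision, propagates follow-up waves through
#' the VAR(1) transition matrix plus covariate effects and fresh residual
#' noise, and applies monotone dropout whose log-odds are linear in the
#' baseline depression score (so with a positive slope, completers have
#' lower baseline severity than non-completers in expectation).
#'
#' @param truth a [make_ground_truth()] object.
#' @param n0 baseline sample size (>= 10).
#' @param waves number of waves, 2 or 3.
#' @param seed integer; the single source of randomness.
#'
#' @return A `panel_data` data frame in long format, one row per
#'   participant-wave, with columns `participant_id`, `wave` (`"T0"`,
#'   `"T1"`, ...), the nine symptom columns and the four covariates.
#'   Symptom cells are `NA` from a participant's dropout wave onward.
#' @export
#' @examples
#' panel <- simulate_panel(default_ground_truth(), n0 = 100, waves = 3, seed = 7)
#' table(panel$wave, complete = stats::complete.cases(panel[symptom_labels()]))
simulate_panel <- function(truth, n0, waves = 3, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n0 < 10) stopf("n0 must be >= 10 (got %d)", n0)
  if (!waves %in% c(2, 3)) stopf("waves must be 2 or 3")

  p <- length(truth$labels)
  L <- chol(truth$sigma_resid)   # upper triangular: z %*% L has cov sigma
  B <- truth$transition
  icpt <- truth$attrition_intercept
  if (length(icpt) == 1) icpt <- rep(icpt, waves - 1)
  if (length(icpt) < waves - 1) stopf("attrition_intercept must have length 1 or waves-1")

  with_seed(seed, {
    covs <- data.frame(
      age = runif(n0, 15, 24),
      gender = rbinom(n0, 1, 0.5),
      education = sample.int(4, n0, replace = TRUE),
      duration = rexp(n0, rate = 1 / 2.2)
    )
    cov_shift <- as.matrix(covs) %*% truth$covariate_effects

    scores <- vector("list", waves)
    scores[[1]] <- matrix(rnorm(n0 * p), n0, p) %*% L
    colnames(scores[[1]]) <- truth$labels
    for (w in 2:waves) {
      resid <- matrix(rnorm(n0 * p), n0, p) %*% L * sqrt(truth$noise_scale)
      scores[[w]] <- scores[[w - 1]] %*% B + cov_shift + resid
      colnames(scores[[w]]) <- truth$labels
    }

    # monotone dropout: one uniform draw per participant per follow-up wave,
    # in a fixed stream so attrition is comparable across slope settings
    u <- matrix(runif(n0 * (waves - 1)), n0, waves - 1)
    base_dep <- scores[[1]][, 1]
    present <- matrix(TRUE, n0, waves)
    for (w in 2:waves) {
      p_drop <- plogis(icpt[w - 1] + truth$attrition_slope * base_dep)
      dropped <- u[, w - 1] < p_drop
      present[, w] <- present[, w - 1] & !dropped
    }

    rows <- vector("list", waves)
    for (w in seq_len(waves)) {
      sc <- scores[[w]]
      sc[!present[, w], ] <- NA_real_
      rows[[w]] <- data.frame(
        participant_id = sprintf("P%05d", seq_len(n0)),
        wave = paste0("T", w - 1),
        as.data.frame(sc),
        covs,
        check.names = FALSE
      )
    }
    panel <- do.call(rbind, rows)
    panel <- panel[order(panel$participant_id, panel$wave), ]
    rownames(panel) <- NULL
    as_panel_data(panel, labels = truth$labels)
  })
}

#' Mark a data frame as a symptom panel
#'
#' Validates the long panel layout (one row per participant-wave, symptom
#' and covariate columns present) and attaches the `panel_data` class. No
#' monotone-missingness requirement is imposed: real cohorts may return
#' after a missed wave.
#'
#' @param df data frame with columns `participant_id`, `wave`, the symptom
#'   columns in `labels`, and the covariates in `covariates`.
#' @param labels symptom column names.
#' @param covariates covariate column names.
#' @return `df` with class `panel_data` and attributes `labels`,
#'   `covariates`, `waves`.
#' @export
as_panel_data <- function(df, labels = symptom_labels(),
                          covariates = covariate_labels()) {
  missing_cols <- setdiff(c("participant_id", "wave", labels, covariates), names(df))
  if (length(missing_cols)) {
    stopf("panel is missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$participant_id, df$wave)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stopf(
      "duplicate (participant, wave) record(s): %s",
      paste(utils::head(dup, 5), collapse = "; ")
    )
  }
  structure(
    df,
    labels = labels,
    covariates = covariates,
    waves = sort(unique(as.character(df$wave))),
    class = c("panel_data", "data.frame")
  )
}

#' @export
print.panel_data <- function(x, ...) {
  labs <- attr(x, "labels")
  waves <- attr(x, "waves")
  cat(sprintf(
    "panel_data: %d participants, %d waves (%s), %d symptom domains\n",
    length(unique(x$participant_id)), length(waves),
    paste(waves, collapse = ", "), length(labs)
  ))
  for (w in waves) {
    sub <- x[x$wave == w, labs, drop = FALSE]
    cat(sprintf("  %s: %d complete cases of %d rows\n",
                w, sum(stats::complete.cases(sub)), nrow(sub)))
  }
  invisible(x)
}

# complete-case score matrix for one wave (symptoms only)
wave_scores <- function(panel, wave, labels = attr(panel, "labels")) {
  sub <- panel[panel$wave == wave, , drop = FALSE]
  if (!nrow(sub)) stopf("wave '%s' not present in panel", wave)
  m <- as.matrix(sub[, labels, drop = FALSE])
  rownames(m) <- sub$participant_id
  m
}
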