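#' Construct a known data-generating structure for panel simulation
#'
#' Builds a `ground_truth` object holding (i) a contemporaneous residual
#' precision matrix parameterized by requested partial correlations and
#' (ii) a lagged (VAR(1)) transition matrix with a common autoregressive
#' diagonal plus requested cross-lagged entries. Downstream estimators are
#' validated against this structure.
#'
#' The precision matrix starts from the identity; each requested partial
#' correlation rho between nodes i and j enters as -rho in the off-diagonal.
#' If the smallest eigenvalue of the result falls below 0.05 a minimal ridge
#' is added to the diagonal so that it equals 0.05, which guarantees positive
#' definiteness at the cost of slightly shrinking the implied partials; the
#' exact implied partial correlations are recomputed and stored in
#' `$partials_implied`.
#'
#' @param edge_spec list of `list(i, j, rho)` (or 3-element vectors) giving
#'   node labels/indices and the requested partial correlation in (-1, 1).
#' @param transition_spec list of `list(from, to, coef)` cross-lagged
#'   entries of the transition matrix (rows = predictor at t-1, columns =
#'   outcome at t).
#' @param autoregressive common diagonal of the transition matrix.
#' @param labels node labels; defaults to [symptom_labels()].
#' @param covariate_effects 4 x 9 matrix of covariate effects on the wave
#'   means (rows follow [covariate_labels()]); defaults to zero.
#' @param attrition_intercept,attrition_slope logistic dropout parameters:
#'   at each follow-up wave a still-present participant drops out with
#'   probability `plogis(intercept + slope * baseline depression)`.
#'   `attrition_intercept` may be a vector (one per follow-up wave) and
#'   `-Inf` disables dropout.
#' @param noise_scale multiplier on the residual covariance of follow-up
#'   waves (wave 0 always uses the unscaled implied covariance).
#' @param seed integer recorded with the object (simulation seeds are passed
#'   separately to [simulate_panel()]).
#'
#' @return A `ground_truth` object with elements `labels`,
#'   `precision_resid`, `sigma_resid`, `partials_implied`, `transition`,
#'   `covariate_effects`, `attrition_intercept`, `attrition_slope`,
#'   `noise_scale`, `ridge`, `seed`.
#' @export
#' @examples
#' gt <- make_ground_truth(
#'   edge_spec = list(list("SuI", "SuT", 0.4)),
#'   transition_spec = list(list("AcS", "SOM", 0.4)),
#'   autoregressive = 0.3
#' )
#' gt$partials_implied["SuI", "SuT"]
make_ground_truth <- function(edge_spec = list(),
                              transition_spec = list(),
                              autoregressive = 0,
                              labels = symptom_labels(),
                              covariate_effects = NULL,
                              attrition_intercept = -Inf,
                              attrition_slope = 0,
                              noise_scale = 1,
                              seed = 1L) {
  p <- length(labels)
  stopifnot(p >= 2, noise_scale > 0)

  idx <- function(x) {
    if (is.character(x)) {
      m <- match(x, labels)
      if (is.na(m)) stopf("unknown node label '%s'", x)
      m
    } else {
      as.integer(x)
    }
  }

  K <- diag(p)
  seen <- character(0)
  for (e in edge_spec) {
    i <- idx(e[[1]]); j <- idx(e[[2]]); rho <- as.numeric(e[[3]])
    if (i == j) stopf("edge_spec entry connects node %d to itself", i)
    if (abs(rho) >= 1) stopf("partial correlation %.3f outside (-1, 1)", rho)
    key <- paste(sort(c(i, j)), collapse = "-")
    if (key %in% seen) stopf("duplicate edge in edge_spec: %s-%s", labels[i], labels[j])
    seen <- c(seen, key)
    K[i, j] <- K[j, i] <- -rho
  }

  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) < 0.05) {
    ridge <- 0.05 - min(ev)
    K <- K + diag(ridge, p)
    ev2 <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) <= 0) {
      stopf(
        "requested partial-correlation structure is not positive definite; eigenvalues: %s",
        paste(sprintf("%.4f", ev), collapse = ", ")
      )
    }
  }
  dimnames(K) <- list(labels, labels)

  # implied partial correlations: -K_ij / sqrt(K_ii K_jj)
  d <- sqrt(diag(K))
  partials <- -K / tcrossprod(d)
  diag(partials) <- 0

  B <- matrix(0, p, p, dimnames = list(labels, labels))
  diag(B) <- autoregressive
  seenb <- character(0)
  for (e in transition_spec) {
    i <- idx(e[[1]]); j <- idx(e[[2]])
    key <- paste(i, j, sep = ">")
    if (key %in% seenb) stopf("duplicate entry in transition_spec: %s->%s", labels[i], labels[j])
    seenb <- c(seenb, key)
    B[i, j] <- as.numeric(e[[3]])
  }
  sr <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (sr >= 1) stopf("transition matrix is unstable (spectral radius %.3f >= 1)", sr)

  if (is.null(covariate_effects)) {
    covariate_effects <- matrix(0, 4, p, dimnames = list(covariate_labels(), labels))
  } else {
    covariate_effects <- as.matrix(covariate_effects)
    stopifnot(nrow(covariate_effects) == 4, ncol(covariate_effects) == p)
    dimnames(covariate_effects) <- list(covariate_labels(), labels)
  }

  structure(
    list(
      labels = labels,
      precision_resid = K,
      sigma_resid = solve(K),
      partials_implied = partials,
      transition = B,
      spectral_radius = sr,
      covariate_effects = covariate_effects,
      attrition_intercept = attrition_intercept,
      attrition_slope = attrition_slope,
      noise_scale = noise_scale,
      ridge = ridge,
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  ne <- sum(abs(x$partials_implied[upper.tri(x$partials_implied)]) > 1e-12)
  nb <- sum(x$transition[row(x$transition) != col(x$transition)] != 0)
  cat(sprintf(
    "ground_truth: %d nodes, %d contemporaneous edges, %d cross-lagged paths\n",
    length(x$labels), ne, nb
  ))
  cat(sprintf(
    "  autoregressive diag %.3g, spectral radius %.3f, ridge %.3g\n",
    mean(diag(x$transition)), x$spectral_radius, x$ridge
  ))
  cat(sprintf(
    "  attrition: intercept %s, slope %.3g on baseline %s\n",
    paste(signif(x$attrition_intercept, 3), collapse = "/"),
    x$attrition_slope, x$labels[1]
  ))
  invisible(x)
}

#' A strongly structured data-generating truth for stability studies
#'
#' A nine-node contemporaneous structure with pronounced hubs (depression
#' and subjective anxiety) and strong, heterogeneous partial correlations,
#' so that node strength varies widely across nodes. Case-dropping
#' stability of centrality is driven by that heterogeneity, which makes
#' this preset the natural benchmark for correlation-stability analyses.
#' No lagged paths and no attrition.
#'
#' @param seed integer recorded with the object.
#' @return A `ground_truth` object.
#' @export
hub_ground_truth <- function(seed = 1L) {
  make_ground_truth(
    edge_spec = list(
      list("DEP", "ANX", 0.45),
      list("DEP", "SQQ", 0.30),
      list("DEP", "SuI", 0.30),
      list("SOM", "ANX", 0.40),
      list("SuI", "SuT", 0.45),
      list("Pas", "AcS", 0.40),
      list("SQQ", "DIS", 0.30),
      list("DIS", "Pas", 0.25),
      list("ANX", "SuT", 0.20)
    ),
    seed = seed
  )
}

#' The default study-like data-generating truth
#'
#' A nine-node three-wave structure mirroring a clinical adolescent
#' depression cohort: strong contemporaneous partial correlations between
#' suicide ideation and suicide tendency, somatic and subjective anxiety,
#' and passive and active sleepiness, a web of moderate edges among the
#' affective and sleep domains, dominant cross-lagged paths from active
#' sleepiness to somatic symptoms and depression and from suicide ideation
#' to suicide tendency, moderate autoregression, and dropout whose
#' probability increases with baseline depression (calibrated to retain
#' roughly 650/460/280 of the baseline sample across the three waves).
#'
#' @param seed integer recorded with the object.
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(seed = 1L) {
  make_ground_truth(
    edge_spec = list(
      list("SuI", "SuT", 0.40),
      list("SOM", "ANX", 0.35),
      list("Pas", "AcS", 0.35),
      list("DEP", "ANX", 0.20),
      list("DEP", "SuI", 0.20),
      list("DEP", "SQQ", 0.15),
      list("SQQ", "DIS", 0.25),
      list("DIS", "Pas", 0.15),
      list("SOM", "SQQ", 0.15)
    ),
    transition_spec = list(
      list("AcS", "SOM", 0.40),
      list("AcS", "DEP", 0.35),
      list("SuI", "SuT", 0.40),
      list("SuT", "SuI", 0.20),
      list("ANX", "DEP", 0.15)
    ),
    autoregressive = 0.3,
    attrition_intercept = c(-0.95, -0.45),
    attrition_slope = 0.30,
    seed = seed
  )
}
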