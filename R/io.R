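#' Read a symptom panel from a wide CSV
#'
#' One row per participant-wave; empty cells are missing. Column names are
#' resolvable via `labels`/`covariates`. Non-monotone missingness is
#' accepted. Unparseable numeric cells are reported with their coordinates.
#'
#' @param path CSV file path.
#' @param labels,covariates expected symptom / covariate column names.
#' @return A [as_panel_data()] object.
#' @export
read_panel_csv <- function(path, labels = symptom_labels(),
                           covariates = covariate_labels()) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  missing_cols <- setdiff(c("participant_id", "wave", labels, covariates), names(df))
  if (length(missing_cols)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  for (col in c(labels, covariates)) {
    raw <- df[[col]]
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stopf("%s: unparseable numeric cell at row %d, column '%s' ('%s')",
            path, bad[1] + 1L, col, raw[bad[1]])
    }
    df[[col]] <- val
  }
  as_panel_data(df, labels = labels, covariates = covariates)
}

#' Write a symptom panel to CSV
#'
#' Inverse of [read_panel_csv()]; missing symptom cells become empty fields.
#'
#' @param panel a `panel_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a ground-truth structure as JSON
#'
#' @param truth a [make_ground_truth()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      labels = truth$labels,
      precision_resid = truth$precision_resid,
      partials_implied = truth$partials_implied,
      transition = truth$transition,
      covariate_effects = truth$covariate_effects,
      attrition_intercept = truth$attrition_intercept,
      attrition_slope = truth$attrition_slope,
      noise_scale = truth$noise_scale,
      ridge = truth$ridge,
      seed = truth$seed
    ),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' Export an undirected network fit as JSON
#'
#' Serializes node labels, the dense partial-correlation matrix, the
#' selected penalty and the sample size.
#'
#' @param fit a `ggm_fit` object from [ebic_select()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      labels = fit$labels, W = fit$W, lambda = fit$lambda_selected,
      gamma = fit$gamma, n = fit$n
    ),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' Export an edge list as CSV
#'
#' For symmetric matrices, upper-triangle edges `(node_i, node_j, weight)`;
#' for directed coefficient matrices, all ordered pairs `(from, to, weight,
#' autoregressive)`. With `display = TRUE` only edges with absolute weight
#' above `display_threshold` are written — a plotting convention, never
#' applied to analysis matrices.
#'
#' @param M square weight matrix with dimnames.
#' @param path output file path.
#' @param directed whether `M` is a directed coefficient matrix.
#' @param display apply the display threshold filter.
#' @param display_threshold absolute-weight cutoff used when `display=TRUE`.
#' @return The exported data frame, invisibly.
#' @export
write_edgelist_csv <- function(M, path, directed = FALSE, display = FALSE,
                               display_threshold = 0.1) {
  labs <- rownames(M)
  if (directed) {
    idx <- which(matrix(TRUE, nrow(M), ncol(M)), arr.ind = TRUE)
    df <- data.frame(
      from = labs[idx[, 1]], to = labs[idx[, 2]],
      weight = M[idx], autoregressive = idx[, 1] == idx[, 2]
    )
  } else {
    idx <- which(upper.tri(M), arr.ind = TRUE)
    df <- data.frame(node_i = labs[idx[, 1]], node_j = labs[idx[, 2]], weight = M[idx])
  }
  if (display) df <- df[abs(df$weight) > display_threshold, , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
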