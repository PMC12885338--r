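#' Configuration for the full analysis pipeline
#'
#' Bundles every tuning constant and seed so that all outputs carry full
#' provenance.
#'
#' @param input path to a panel CSV (or `NULL` when a `panel_data` object
#'   is passed to [run_full_pipeline()] directly).
#' @param output_dir directory for result files.
#' @param labels,covariates column names.
#' @param gamma EBIC hyperparameter.
#' @param n_lambda,lambda_min_ratio penalty grid for the per-wave networks.
#' @param bootstrap_B bootstrap replicates for edge CIs.
#' @param nct_permutations permutations per wave-pair comparison.
#' @param cs_drop_grid,cs_subsamples case-dropping stability settings.
#' @param mi_m multiple-imputation datasets (sensitivity stage; run only
#'   when the panel has missing symptom cells).
#' @param seed master seed for every stochastic stage.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL,
                            output_dir = "panelnet-results",
                            labels = symptom_labels(),
                            covariates = covariate_labels(),
                            gamma = 0.5,
                            n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            bootstrap_B = 1000,
                            nct_permutations = 1000,
                            cs_drop_grid = seq(0.05, 0.75, by = 0.05),
                            cs_subsamples = 100,
                            mi_m = 20,
                            seed = 1L) {
  structure(
    list(
      input = input, output_dir = output_dir, labels = labels,
      covariates = covariates, gamma = gamma, n_lambda = n_lambda,
      lambda_min_ratio = lambda_min_ratio, bootstrap_B = bootstrap_B,
      nct_permutations = nct_permutations, cs_drop_grid = cs_drop_grid,
      cs_subsamples = cs_subsamples, mi_m = mi_m, seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

# hash of the scientific configuration only: file-system locations do not
# change the analysis, so they are excluded from the fingerprint
config_hash <- function(config) {
  sci <- unclass(config)
  sci$input <- NULL
  sci$output_dir <- NULL
  fnv1a_hash(jsonlite::toJSON(sci, auto_unbox = TRUE, digits = NA))
}

log_stage <- function(fmt, ...) {
  message(sprintf("[panelnet %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full longitudinal network analysis
#'
#' Executes, on one panel: per-wave EBIC-selected partial-correlation
#' networks with centrality tables; all pairwise permutation invariance
#' tests with Bonferroni adjustment over the family; cross-lagged networks
#' for consecutive wave pairs with directed expected influence; bootstrap
#' edge confidence intervals and case-dropping CS coefficients per
#' network; and, when the panel contains missing symptom cells, the
#' multiple-imputation sensitivity stage. Artifacts are written to
#' `config$output_dir` along with a manifest holding the config, its hash
#' and the master seed; a stage that fails is isolated (recorded in the
#' manifest, downstream artifacts absent) without corrupting the others.
#'
#' @param config an [analysis_config()].
#' @param panel optional `panel_data`; read from `config$input` otherwise.
#' @return Invisibly, a list with all in-memory results (`analysis`,
#'   `nct`, `boot`, `cs`, `sensitivity`, `manifest`).
#' @export
run_full_pipeline <- function(config, panel = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(panel)) {
    if (is.null(config$input)) stopf("config$input or a panel object is required")
    panel <- read_panel_csv(config$input, config$labels, config$covariates)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = list(),
    artifacts = character(0)
  )
  failed <- character(0)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      log_stage("stage '%s' FAILED: %s", name, conditionMessage(e))
      failed <<- c(failed, name)
      structure(list(message = conditionMessage(e)), class = "stage_failure")
    })
    manifest$stages[[name]] <<- list(
      status = if (inherits(res, "stage_failure")) "failed" else "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    )
    log_stage("stage '%s': %s (%.1fs)", name, manifest$stages[[name]]$status,
              manifest$stages[[name]]$seconds)
    res
  }
  waves <- attr(panel, "waves")

  analysis <- run_stage("networks", analyze_networks(
    panel, gamma = config$gamma, seed = config$seed,
    n_lambda = config$n_lambda, lambda_min_ratio = config$lambda_min_ratio
  ))
  if (inherits(analysis, "stage_failure")) {
    stopf("network estimation failed: %s", analysis$message)
  }
  for (w in waves) {
    write_network_json(analysis$ggm[[w]], out(sprintf("ggm_%s.json", w)))
    write_edgelist_csv(analysis$W[[w]], out(sprintf("edges_%s.csv", w)))
    cen <- analysis$centrality[[w]]
    cen$wave <- w
    write.csv(cen, out(sprintf("centrality_%s.csv", w)), row.names = FALSE)
  }
  for (pair in names(analysis$A)) {
    tag <- gsub("->", "_to_", pair, fixed = TRUE)
    fit <- analysis$clpn[[pair]]
    jsonlite::write_json(
      list(A = fit$A, covariate_coefs = fit$covariate_coefs,
           n = fit$n_complete, seed = fit$seed, wave_pair = fit$wave_pair,
           config_hash = manifest$config_hash),
      out(sprintf("clpn_%s.json", tag)),
      digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
    )
    write_edgelist_csv(fit$A, out(sprintf("clpn_edges_%s.csv", tag)), directed = TRUE)
    write.csv(analysis$dcentrality[[pair]],
              out(sprintf("clpn_centrality_%s.csv", tag)), row.names = FALSE)
  }

  # pairwise invariance tests over every wave pair, Bonferroni family = #pairs
  nct_res <- run_stage("nct", {
    pairs <- utils::combn(waves, 2, simplify = FALSE)
    scores <- lapply(waves, function(w) center_within_wave(panel, w)$scores)
    names(scores) <- waves
    res <- lapply(seq_along(pairs), function(k) {
      pr <- pairs[[k]]
      nct(scores[[pr[1]]], scores[[pr[2]]],
          n_permutations = config$nct_permutations, gamma = config$gamma,
          seed = derive_seed(config$seed, 200 + k),
          n_lambda = config$n_lambda, lambda_min_ratio = config$lambda_min_ratio)
    })
    names(res) <- vapply(pairs, paste, "", collapse = "_vs_")
    m <- length(res)
    report <- lapply(res, function(r) list(
      M_observed = r$M_observed, S_observed = r$S_observed,
      p_structure = r$p_structure, p_global = r$p_global,
      p_structure_bonferroni = bonferroni(r$p_structure, m),
      p_global_bonferroni = bonferroni(r$p_global, m),
      n_permutations = r$n_permutations, seed = r$seed,
      note = "waves permuted as independent groups; participant overlap ignored"
    ))
    jsonlite::write_json(
      list(comparisons = report, family_size = m,
           config_hash = manifest$config_hash, seed = config$seed),
      out("nct.json"), digits = NA, auto_unbox = TRUE
    )
    res
  })

  boot <- run_stage("bootstrap", {
    res <- list()
    for (w in waves) {
      scores <- center_within_wave(panel, w)$scores
      bd <- bootstrap_estimates(
        scores, ggm_boot_estimator(config$gamma, n_lambda = config$n_lambda,
                                   lambda_min_ratio = config$lambda_min_ratio),
        B = config$bootstrap_B, seed = derive_seed(config$seed, 300 + match(w, waves))
      )
      ci <- edge_ci(bd, 0.95)
      write.csv(ci, out(sprintf("edge_ci_%s.csv", w)), row.names = FALSE)
      res[[w]] <- list(dist = bd, ci = ci,
                       diff_edges = difference_tests(bd, "edges"),
                       diff_strength = difference_tests(bd, "strength"))
    }
    res
  })

  cs <- run_stage("stability", {
    res <- list()
    for (w in waves) {
      scores <- center_within_wave(panel, w)$scores
      res[[w]] <- case_dropping_cs(
        scores, ggm_boot_estimator(config$gamma, n_lambda = config$n_lambda,
                                   lambda_min_ratio = config$lambda_min_ratio),
        drop_grid = config$cs_drop_grid, n_subsamples = config$cs_subsamples,
        seed = derive_seed(config$seed, 400 + match(w, waves))
      )
    }
    jsonlite::write_json(
      list(
        cs = lapply(res, function(r) list(
          cs_coefficient = as.list(r$cs_coefficient),
          band = as.list(r$band),
          drop_grid = r$drop_grid,
          prob_ge_070 = r$prob_ge_070
        )),
        bands = list(excellent = "> 0.50", moderate = "0.25-0.50",
                     insufficient = "< 0.25"),
        config_hash = manifest$config_hash, seed = config$seed
      ),
      out("stability.json"), digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
    )
    res
  })

  has_missing <- anyNA(panel[, config$labels])
  sensitivity <- NULL
  if (has_missing) {
    sensitivity <- run_stage("sensitivity", {
      imp <- impute_chained(panel, m = config$mi_m,
                            seed = derive_seed(config$seed, 500))
      pooled <- pooled_networks(imp, gamma = config$gamma, seed = config$seed,
                                n_lambda = config$n_lambda,
                                lambda_min_ratio = config$lambda_min_ratio)
      rep <- compare_spearman(analysis, pooled)
      write.csv(rep, out("sensitivity_spearman.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(spearman = rep, m = imp$m, method = imp$method,
             config_hash = manifest$config_hash, seed = config$seed),
        out("sensitivity.json"), digits = NA, auto_unbox = TRUE
      )
      list(imputation = imp, pooled = pooled, report = rep)
    })
  } else {
    manifest$stages[["sensitivity"]] <- list(status = "skipped (no missing cells)")
  }

  manifest$artifacts <- list.files(config$output_dir)
  jsonlite::write_json(manifest, out("manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  if (length(failed)) {
    warning(sprintf("pipeline stage(s) failed: %s", paste(failed, collapse = ", ")))
  }
  invisible(list(
    analysis = analysis,
    nct = if (!inherits(nct_res, "stage_failure")) nct_res,
    boot = if (!inherits(boot, "stage_failure")) boot,
    cs = if (!inherits(cs, "stage_failure")) cs,
    sensitivity = if (!inherits(sensitivity, "stage_failure")) sensitivity,
    manifest = manifest,
    failed = failed
  ))
}
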