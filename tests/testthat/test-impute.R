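# impose missing-at-random deletion of whole follow-up waves, with dropout
# probability increasing in the baseline depression score
delete_mar <- function(panel, wave, rate = 0.2, seed = 1) {
  labs <- attr(panel, "labels")
  t0 <- panel[panel$wave == "T0", ]
  lin <- scale(t0$DEP)[, 1]
  p <- plogis(qlogis(rate) + 1.0 * lin)
  out <- as.data.frame(panel)
  set.seed(seed)
  drop_ids <- t0$participant_id[runif(nrow(t0)) < p]
  out[out$wave == wave & out$participant_id %in% drop_ids, labs] <- NA
  as_panel_data(out)
}

complete_panel <- function(n = 250, seed = 1) {
  gt <- make_ground_truth(
    edge_spec = list(list("SuI", "SuT", 0.4), list("SOM", "ANX", 0.35),
                     list("DEP", "ANX", 0.25)),
    transition_spec = list(list("AcS", "SOM", 0.4)),
    autoregressive = 0.3, attrition_intercept = -Inf
  )
  simulate_panel(gt, n, 2, seed = seed)
}

test_that("a complete panel is returned unchanged by imputation", {
  panel <- complete_panel(60)
  imp <- impute_chained(panel, m = 3, seed = 2)
  for (d in imp$datasets) {
    expect_equal(as.data.frame(d), as.data.frame(panel))
  }
})

test_that("imputation preserves observed cells bit-exactly and is deterministic", {
  panel <- delete_mar(complete_panel(150, 3), "T1", rate = 0.25, seed = 3)
  labs <- symptom_labels()
  obs <- !is.na(as.matrix(panel[, labs]))
  imp1 <- impute_chained(panel, m = 2, seed = 9)
  imp2 <- impute_chained(panel, m = 2, seed = 9)
  for (k in 1:2) {
    filled <- as.matrix(imp1$datasets[[k]][, labs])
    expect_identical(filled[obs], as.matrix(panel[, labs])[obs])
    expect_false(anyNA(filled))
    expect_identical(filled, as.matrix(imp2$datasets[[k]][, labs]))
  }
})

test_that("imputed cells recover the masked truth on average", {
  full <- complete_panel(400, 5)
  labs <- symptom_labels()
  masked <- delete_mar(full, "T1", rate = 0.2, seed = 6)
  holes <- is.na(as.matrix(masked[, labs]))
  imp <- impute_chained(masked, m = 5, seed = 7)
  truth_vals <- as.matrix(full[, labs])[holes]
  imp_means <- Reduce(`+`, lapply(imp$datasets, function(d) {
    as.matrix(d[, labs])[holes]
  })) / imp$m
  pooled_sd <- sd(truth_vals)
  expect_lt(abs(mean(imp_means) - mean(truth_vals)), 0.15 * pooled_sd)
})

test_that("over-missing columns and incomplete covariates are refused", {
  panel <- complete_panel(60)
  broken <- as.data.frame(panel)
  broken$age[3] <- NA
  expect_error(impute_chained(as_panel_data(broken), m = 2, seed = 1),
               "covariates")

  mostly_gone <- as.data.frame(panel)
  t1_rows <- mostly_gone$wave == "T1"
  mostly_gone$DEP[t1_rows][seq_len(floor(0.9 * sum(t1_rows)))] <- NA
  expect_error(impute_chained(as_panel_data(mostly_gone), m = 2, seed = 1),
               "80%")
})

test_that("pooling with m = 1 or with no missingness is an identity", {
  panel <- complete_panel(150, 8)
  original <- analyze_networks(panel, seed = 4, clpn = FALSE)
  imp <- impute_chained(panel, m = 3, seed = 2)
  pooled <- pooled_networks(imp, seed = 4, clpn = FALSE)
  expect_equal(pooled$W, original$W, tolerance = 1e-12)

  imp1 <- impute_chained(delete_mar(panel, "T1", 0.2, 2), m = 1, seed = 3)
  single <- analyze_networks(imp1$datasets[[1]], seed = 4, clpn = FALSE)
  pooled1 <- pooled_networks(imp1, seed = 4, clpn = FALSE)
  expect_equal(pooled1$W, single$W, tolerance = 1e-12)
})

test_that("Spearman comparison matches a rank-then-Pearson oracle", {
  panel <- complete_panel(200, 10)
  a <- analyze_networks(panel, seed = 1)
  jitter_p <- as.data.frame(panel)
  set.seed(2)
  labs <- symptom_labels()
  jitter_p[, labs] <- jitter_p[, labs] + matrix(
    rnorm(nrow(jitter_p) * 9, sd = 0.2), ncol = 9
  )
  b <- analyze_networks(as_panel_data(jitter_p), seed = 1)
  rep <- compare_spearman(a, b)
  expect_true(all(rep$spearman >= -1 & rep$spearman <= 1, na.rm = TRUE))

  # identical analyses: perfect agreement everywhere
  self <- compare_spearman(a, a)
  expect_equal(self$spearman[!is.na(self$spearman)],
               rep(1, sum(!is.na(self$spearman))))

  # oracle: Spearman = Pearson on mid-ranks, for the edge comparison
  wa <- upper_tri_values(a$W[["T0"]])
  wb <- upper_tri_values(b$W[["T0"]])
  expect_equal(
    rep$spearman[rep$comparison == "edge_weights" & rep$wave == "T0"],
    cor(rank(wa), rank(wb))
  )
})
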