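test_that("within-wave centring produces zero-mean complete-case moments", {
  gt <- default_ground_truth()
  panel <- simulate_panel(gt, 400, 3, seed = 2)
  cw <- center_within_wave(panel, "T1")
  expect_true(all(abs(colMeans(cw$scores)) < 1e-12))
  expect_equal(cw$moments$n, nrow(cw$scores))
  expect_equal(cw$n_excluded, sum(panel$wave == "T1") - cw$moments$n)
  expect_equal(unname(diag(cw$moments$S)), rep(1, 9))

  # idempotence: centring already-centred scores changes nothing
  centred <- panel
  for (w in attr(panel, "waves")) {
    rows <- centred$wave == w
    sub <- as.matrix(centred[rows, symptom_labels()])
    cc <- complete.cases(sub)
    sub[cc, ] <- scale(sub[cc, ], center = TRUE, scale = FALSE)
    centred[rows, symptom_labels()] <- sub
  }
  cw2 <- center_within_wave(as_panel_data(as.data.frame(centred)), "T1")
  expect_equal(cw2$scores, cw$scores, tolerance = 1e-12)
})

test_that("degenerate wave inputs are rejected with informative errors", {
  gt <- default_ground_truth()
  panel <- simulate_panel(gt, 60, 2, seed = 3)
  flat <- panel
  flat$SQQ <- 1
  expect_error(center_within_wave(as_panel_data(as.data.frame(flat)), "T0"),
               "SQQ")
  tiny <- panel[panel$participant_id %in% sprintf("P%05d", 1:8), ]
  expect_error(center_within_wave(as_panel_data(as.data.frame(tiny)), "T0"),
               "complete cases")
})

test_that("penalized precision estimation matches its analytic limits", {
  set.seed(101)
  S <- random_cor_matrix(9)
  # lambda = 0: direct inversion
  K0 <- graphical_lasso(S, 0, tol = 1e-9, max_iter = 500)
  expect_lt(max(abs(K0 - solve(S))), 1e-6)
  # identity input stays identity at any penalty
  expect_equal(max(abs(graphical_lasso(diag(9), 0.3) - diag(9))), 0)
  # full shrinkage: penalty above the largest off-diagonal empties the graph
  Kd <- graphical_lasso(S, max(abs(S[upper.tri(S)])) + 1e-3)
  expect_true(all(Kd[upper.tri(Kd)] == 0))
  expect_error(graphical_lasso(S, -0.1))
})

test_that("EBIC selection returns a coherent fit object", {
  gt <- default_ground_truth()
  panel <- simulate_panel(gt, 650, 2, seed = 4)
  fit <- fit_wave_ggm(panel, "T0")

  expect_s3_class(fit, "ggm_fit")
  expect_true(isSymmetric(fit$W))
  expect_equal(unname(diag(fit$W)), rep(0, 9))
  expect_true(all(abs(fit$W) < 1))
  # zero pattern of W mirrors K, and signs match -K
  expect_identical(fit$W == 0, fit$K == 0 | row(fit$K) == col(fit$K))
  offd <- row(fit$K) != col(fit$K)
  expect_true(all(sign(fit$W[offd]) == sign(-fit$K[offd])))
  # the selected lambda minimizes the recorded EBIC trace
  expect_equal(min(fit$ebic_trace$ebic),
               fit$ebic_trace$ebic[fit$ebic_trace$lambda == fit$lambda_selected])
})

test_that("edge counts shrink monotonically with the penalty", {
  # counted above a small numerical floor: support flips of coefficients at
  # the order of the solver tolerance are not meaningful edges
  gt <- default_ground_truth()
  panel <- simulate_panel(gt, 650, 2, seed = 4)
  S <- center_within_wave(panel, "T0")$moments$S
  lam_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lam_max), log(lam_max * 0.01), length.out = 30))
  counts <- vapply(lambdas, function(l) {
    K <- graphical_lasso(S, l)
    sum(abs(K[upper.tri(K)]) > 1e-4)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))  # lambda decreasing along the grid
})

test_that("gamma = 0 (BIC) never selects a sparser graph than gamma = 0.5", {
  gt <- default_ground_truth()
  panel <- simulate_panel(gt, 300, 2, seed = 8)
  m <- center_within_wave(panel, "T0")$moments
  e_bic <- sum(ebic_select(m, gamma = 0)$W[upper.tri(diag(9))] != 0)
  e_ebic <- sum(ebic_select(m, gamma = 0.5)$W[upper.tri(diag(9))] != 0)
  expect_gte(e_bic, e_ebic)
})

test_that("selected partial correlations at lambda -> 0 match direct inversion", {
  set.seed(77)
  x <- matrix(rnorm(500 * 9), 500, 9)
  colnames(x) <- symptom_labels()
  S <- cor(x)
  K <- graphical_lasso(S, 0, tol = 1e-9, max_iter = 500)
  d <- sqrt(diag(K))
  W <- -K / tcrossprod(d)
  diag(W) <- 0
  Wo <- sample_partials(scale(x, scale = FALSE))
  expect_lt(max(abs(W - Wo)), 1e-6)
})

test_that("edge weights are recovered from study-scale simulated data", {
  gt <- default_ground_truth()  # true partials between 0.15 and 0.40
  true_w <- upper_tri_values(gt$partials_implied)
  cors <- vapply(1:20, function(s) {
    panel <- simulate_panel(gt, 650, 2, seed = 1000 + s)
    fit <- fit_wave_ggm(panel, "T0")
    cor(upper_tri_values(fit$W), true_w)
  }, numeric(1))
  expect_gte(mean(cors), 0.85)
})
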