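test_that("ground truth construction honours requested structure", {
  # identity case
  gt0 <- make_ground_truth()
  expect_equal(unname(gt0$precision_resid), diag(9))
  expect_equal(unname(gt0$transition), matrix(0, 9, 9))

  # requested partial is reproduced exactly when no ridge is needed
  gt <- single_edge_truth(0.4)
  expect_equal(gt$ridge, 0)
  expect_equal(gt$partials_implied["SuI", "SuT"], 0.4, tolerance = 1e-8)
  off <- gt$partials_implied
  off["SuI", "SuT"] <- off["SuT", "SuI"] <- 0
  expect_true(all(abs(off) < 1e-10))

  # the implied partials must agree with re-inverting the implied covariance
  K_back <- solve(gt$sigma_resid)
  d <- sqrt(diag(K_back))
  P_back <- -K_back / tcrossprod(d)
  diag(P_back) <- 0
  expect_equal(P_back, gt$partials_implied, tolerance = 1e-10)

  # transition assembly and stability check
  gt2 <- three_path_truth()
  expect_equal(unname(diag(gt2$transition)), rep(0.3, 9))
  expect_equal(gt2$transition["AcS", "SOM"], 0.4)
  expect_lt(gt2$spectral_radius, 1)
  expect_equal(
    gt2$spectral_radius,
    max(Mod(eigen(gt2$transition, only.values = TRUE)$values))
  )
})

test_that("degenerate ground-truth requests are rejected", {
  expect_error(
    make_ground_truth(edge_spec = list(list("SuI", "SuT", 1.2))),
    "outside"
  )
  expect_error(
    make_ground_truth(edge_spec = list(
      list("SuI", "SuT", 0.4), list("SuT", "SuI", 0.2)
    )),
    "duplicate"
  )
  expect_error(make_ground_truth(autoregressive = 1.05), "spectral radius")
})

test_that("heavily loaded edge requests trigger the positive-definiteness ridge", {
  gt <- make_ground_truth(edge_spec = list(
    list("DEP", "SOM", 0.8), list("DEP", "ANX", 0.8), list("DEP", "SQQ", 0.8),
    list("SOM", "ANX", -0.8)
  ))
  expect_gt(gt$ridge, 0)
  ev <- eigen(gt$precision_resid, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.05 - 1e-10)
})

test_that("simulated panels are reproducible and attrition-free when disabled", {
  gt <- default_ground_truth()
  p1 <- simulate_panel(gt, 80, 3, seed = 5)
  p2 <- simulate_panel(gt, 80, 3, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_panel(gt, 80, 3, seed = 6)))

  gt_nodrop <- make_ground_truth(attrition_intercept = -Inf)
  full <- simulate_panel(gt_nodrop, 50, 3, seed = 5)
  expect_false(anyNA(full[symptom_labels()]))
})

test_that("dropout is monotone and tied to baseline depression", {
  gt <- make_ground_truth(
    edge_spec = list(list("SuI", "SuT", 0.4)),
    attrition_intercept = -0.8, attrition_slope = 0.5
  )
  panel <- simulate_panel(gt, 4000, 3, seed = 21)
  labs <- symptom_labels()
  wide_na <- sapply(c("T0", "T1", "T2"), function(w) {
    sub <- panel[panel$wave == w, ]
    !complete.cases(sub[, labs])
  })
  # monotone: missing at T1 implies missing at T2
  expect_true(all(wide_na[wide_na[, "T1"], "T2"]))

  # completers have lower baseline depression than non-completers
  t0 <- panel[panel$wave == "T0", ]
  completer <- !wide_na[, "T2"]
  expect_lt(mean(t0$DEP[completer]), mean(t0$DEP[!completer]))
})

test_that("raising the attrition slope weakly reduces completion (shared seed)", {
  # in the convex region of the logistic (per-wave dropout well below 50%)
  # a larger severity slope raises the expected dropout probability; the
  # dropout uniforms share one seeded stream so runs are directly coupled
  counts <- vapply(c(0, 0.4, 0.8, 1.2), function(b) {
    gt <- make_ground_truth(attrition_intercept = -2, attrition_slope = b)
    panel <- simulate_panel(gt, 4000, 3, seed = 99)
    sub <- panel[panel$wave == "T2", symptom_labels()]
    sum(complete.cases(sub))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("wave-0 moments match the implied covariance at large n", {
  gt <- default_ground_truth()
  panel <- simulate_panel(gt, 10000, 2, seed = 31)
  x <- wave0 <- panel[panel$wave == "T0", symptom_labels()]
  S_hat <- cov(as.matrix(x))
  S_true <- gt$sigma_resid
  # entrywise within 3 standard errors (normal-theory SE of a covariance)
  n <- nrow(x)
  se <- sqrt((tcrossprod(diag(S_true)) + S_true^2) / n)
  expect_true(all(abs(S_hat - S_true) <= 3.5 * se))
})

test_that("with zero transition, waves are independent draws", {
  gt <- make_ground_truth(edge_spec = list(list("DEP", "ANX", 0.3)))
  panel <- simulate_panel(gt, 20000, 2, seed = 13)
  a <- as.matrix(panel[panel$wave == "T0", symptom_labels()])
  b <- as.matrix(panel[panel$wave == "T1", symptom_labels()])
  cc <- cor(a, b)
  expect_lt(max(abs(cc)), 0.03)
})

test_that("large-sample wave-0 partial correlation recovers the request", {
  gt <- single_edge_truth(0.4)
  panel <- simulate_panel(gt, 20000, 2, seed = 17)
  x <- as.matrix(panel[panel$wave == "T0", symptom_labels()])
  P <- sample_partials(x)
  expect_equal(P["SuI", "SuT"], 0.4, tolerance = 0.02)
})

test_that("simulation preconditions are enforced", {
  gt <- default_ground_truth()
  expect_error(simulate_panel(gt, 5, 3, seed = 1), "n0")
  expect_error(simulate_panel(gt, 100, 4, seed = 1), "waves")
})
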