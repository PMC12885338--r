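test_that("strength and expected influence follow their summation formulas", {
  W <- toy_network()
  expect_equal(net_strength(W), c(A = 0.75, B = 0.5, C = 0.25))
  expect_equal(expected_influence(W), c(A = 0.75, B = 0.5, C = 0.25))

  # empty network
  expect_equal(unname(net_strength(matrix(0, 4, 4))), rep(0, 4))

  # mixed signs: EI nets out, strength does not
  Wm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  Wm["A", "B"] <- Wm["B", "A"] <- 0.5
  Wm["A", "C"] <- Wm["C", "A"] <- -0.25
  expect_equal(expected_influence(Wm)[["A"]], 0.25)
  expect_equal(net_strength(Wm)[["A"]], 0.75)

  # random signed networks: brute-force row sums; dominance s_i >= |ei_i|
  set.seed(11)
  for (rep in 1:10) {
    W <- random_edge_matrix(9)
    expect_equal(unname(net_strength(W)),
                 unname(apply(W, 1, function(r) sum(abs(r)))))
    expect_equal(unname(expected_influence(W)), unname(apply(W, 1, sum)))
    expect_true(all(net_strength(W) >= abs(expected_influence(W)) - 1e-12))
  }
})

test_that("shortest paths, closeness and betweenness match the toy analysis", {
  W <- toy_network()
  paths <- shortest_paths(W)
  # B-C runs through A: 1/0.5 + 1/0.25 = 6
  expect_equal(paths$d["B", "C"], 6)
  expect_equal(paths$sigma["B", "C"], 1)
  expect_equal(paths$sigma_through["A", "B", "C"], 1)
  expect_equal(closeness(paths), c(A = 1 / 6, B = 1 / 8, C = 1 / 10))
  expect_equal(betweenness(paths), c(A = 1, B = 0, C = 0))
})

test_that("tied shortest paths are counted: equal-weight 4-cycle has sigma = 2", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.5
  W["c", "d"] <- W["d", "c"] <- 0.5
  W["d", "a"] <- W["a", "d"] <- 0.5
  paths <- shortest_paths(W)
  expect_equal(paths$sigma["a", "c"], 2)
  expect_equal(paths$d["a", "c"], 4)
  expect_equal(paths$sigma_through["b", "a", "c"], 1)
  expect_equal(paths$sigma_through["d", "a", "c"], 1)
})

test_that("disconnected components give infinite distance and zero closeness", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.5
  paths <- shortest_paths(W)
  expect_equal(paths$d["a", "c"], Inf)
  expect_equal(paths$sigma["a", "c"], 0)
  expect_equal(unname(closeness(paths)), rep(0, 4))
})

test_that("complete equal-weight triangle has zero betweenness everywhere", {
  W <- matrix(0.4, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(W) <- 0
  expect_equal(unname(betweenness(shortest_paths(W))), rep(0, 3))
})

test_that("closeness and betweenness agree with exhaustive path enumeration", {
  set.seed(202)
  for (rep in 1:15) {
    p <- sample(4:7, 1)
    W <- random_edge_matrix(p, density = 0.5)
    paths <- shortest_paths(W)
    oracle <- enumeration_oracle(W)
    expect_equal(unname(paths$d), oracle$d)
    expect_equal(unname(paths$sigma), oracle$sigma)
    expect_equal(unname(closeness(paths)), oracle$closeness)
    expect_equal(unname(betweenness(paths)), oracle$betweenness)
  }
})

test_that("node relabelling permutes every index identically", {
  set.seed(33)
  W <- random_edge_matrix(7, density = 0.5)
  perm <- sample(7)
  Wp <- W[perm, perm]
  tab <- centrality_table(W)
  tabp <- centrality_table(Wp)
  for (ix in unique(tab$index)) {
    a <- tab$raw[tab$index == ix]
    b <- tabp$raw[tabp$index == ix]
    expect_equal(b, a[perm])
  }
})

test_that("doubling all weights halves distances, doubles closeness, keeps z", {
  set.seed(44)
  W <- random_edge_matrix(6, density = 0.6)
  c1 <- closeness(shortest_paths(W))
  c2 <- closeness(shortest_paths(2 * W))
  expect_equal(c2, 2 * c1)
  t1 <- centrality_table(W)
  t2 <- centrality_table(2 * W)
  expect_equal(t2$z[t2$index == "closeness"], t1$z[t1$index == "closeness"],
               tolerance = 1e-10)
})

test_that("z-scoring uses the n-1 denominator and handles constants", {
  tab <- data.frame(node = c("a", "b", "c"), index = "strength",
                    raw = c(1, 2, 3), z = NA_real_)
  out <- standardize_centrality(tab)
  expect_equal(out$z, c(-1, 0, 1))

  tab$raw <- c(2, 2, 2)
  expect_equal(standardize_centrality(tab)$z, c(0, 0, 0))

  set.seed(5)
  tab$raw <- rnorm(3)
  z <- standardize_centrality(tab)$z
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})
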