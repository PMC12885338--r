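# Independent oracles and small generators used across test files.

# Exhaustive simple-path enumeration over edge lengths 1/|w|: the reference
# for shortest-path distances, path counts, closeness and betweenness on
# small networks (<= 7 nodes). Deliberately brute force and independent of
# the package's Dijkstra implementation.
enumeration_oracle <- function(W, tol = 1e-10) {
  p <- nrow(W)
  len <- ifelse(W == 0, Inf, 1 / abs(W))
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(node, visited, dist) {
      if (node == t) {
        out[[length(out) + 1]] <<- list(dist = dist, via = visited)
        return(invisible())
      }
      for (nxt in seq_len(p)) {
        if (nxt %in% visited || !is.finite(len[node, nxt])) next
        walk(nxt, c(visited, nxt), dist + len[node, nxt])
      }
    }
    walk(s, s, 0)
    out
  }
  d <- matrix(0, p, p)
  sigma <- matrix(0, p, p)
  sigma_through <- array(0, dim = c(p, p, p))
  for (s in seq_len(p)) {
    for (t in seq_len(p)) {
      if (s == t) next
      ps <- paths_between(s, t)
      if (!length(ps)) {
        d[s, t] <- Inf
        next
      }
      dists <- vapply(ps, `[[`, numeric(1), "dist")
      dmin <- min(dists)
      best <- ps[dists <= dmin * (1 + tol) + tol]
      d[s, t] <- dmin
      sigma[s, t] <- length(best)
      for (b in best) {
        inner <- setdiff(b$via, c(s, t))
        for (i in inner) sigma_through[i, s, t] <- sigma_through[i, s, t] + 1
      }
    }
  }
  closeness <- vapply(seq_len(p), function(i) {
    tot <- sum(d[i, -i])
    if (!is.finite(tot) || tot == 0) 0 else 1 / tot
  }, numeric(1))
  btw <- vapply(seq_len(p), function(i) {
    acc <- 0
    for (s in seq_len(p - 1)) {
      for (t in (s + 1):p) {
        if (s == i || t == i || sigma[s, t] == 0) next
        acc <- acc + sigma_through[i, s, t] / sigma[s, t]
      }
    }
    acc
  }, numeric(1))
  list(d = d, sigma = sigma, sigma_through = sigma_through,
       closeness = closeness, betweenness = btw)
}

# random sparse signed symmetric edge matrix
random_edge_matrix <- function(p, density = 0.4, signed = TRUE) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < density) {
        w <- runif(1, 0.1, 0.9) * if (signed && runif(1) < 0.3) -1 else 1
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  dimnames(W) <- list(paste0("n", seq_len(p)), paste0("n", seq_len(p)))
  W
}

# well-conditioned random correlation matrix
random_cor_matrix <- function(p) {
  A <- matrix(rnorm(p * p), p)
  S <- cov2cor(crossprod(A) + diag(p) * 2)
  dimnames(S) <- list(paste0("v", seq_len(p)), paste0("v", seq_len(p)))
  S
}

# the fixed three-node toy used in several formula checks:
# w_AB = 0.5, w_AC = 0.25, w_BC = 0
toy_network <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["A", "C"] <- W["C", "A"] <- 0.25
  W
}

# single-edge contemporaneous truth (SuI-SuT partial 0.4), no lagged paths
single_edge_truth <- function(rho = 0.4) {
  make_ground_truth(edge_spec = list(list("SuI", "SuT", rho)))
}

# lagged-path truth mirroring the dominant early-interval dynamics
three_path_truth <- function() {
  make_ground_truth(
    transition_spec = list(
      list("AcS", "SOM", 0.4), list("AcS", "DEP", 0.35), list("SuI", "SuT", 0.4)
    ),
    autoregressive = 0.3
  )
}

upper_tri_values <- function(M) M[upper.tri(M)]

# sample partial correlations by inverting the sample precision
sample_partials <- function(x) {
  K <- solve(cov(x))
  d <- sqrt(diag(K))
  P <- -K / tcrossprod(d)
  diag(P) <- 0
  P
}
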