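#' Node strength
#'
#' Sum of absolute edge weights incident to each node.
#'
#' @param W symmetric weight matrix with zero diagonal.
#' @return Named numeric vector.
#' @export
net_strength <- function(W) {
  check_edge_matrix(W)
  rowSums(abs(W))
}

#' Node expected influence
#'
#' Signed sum of edge weights incident to each node; equals strength when
#' all incident edges are positive.
#'
#' @param W symmetric weight matrix with zero diagonal.
#' @return Named numeric vector.
#' @export
expected_influence <- function(W) {
  check_edge_matrix(W)
  rowSums(W)
}

check_edge_matrix <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!isSymmetric(unname(W), tol = 1e-10)) stopf("edge matrix must be symmetric")
  if (any(abs(diag(W)) > 1e-12)) stopf("edge matrix must have a zero diagonal")
  invisible(W)
}

#' Weighted shortest paths with path counting
#'
#' Runs Dijkstra's algorithm from every source over edge lengths
#' `1/|w_ij|` (absent edges, `w = 0`, are non-adjacent), counting the
#' number of distinct shortest paths per pair. Path-length ties are detected
#' with a relative tolerance so that the counts are deterministic under
#' floating point. `sigma_through[i, s, t]` counts the shortest s-t paths
#' passing through intermediate node i, obtained from the concatenation rule
#' `sigma(s,i) * sigma(i,t)` when `d(s,i) + d(i,t) = d(s,t)`.
#'
#' @param W symmetric weight matrix with zero diagonal.
#' @param tie_tol relative tolerance for shortest-path-length ties.
#' @return A `shortest_path_table`: list with distance matrix `d` (`Inf`
#'   for disconnected pairs), count matrix `sigma`, and 3-d array
#'   `sigma_through`.
#' @export
shortest_paths <- function(W, tie_tol = 1e-10) {
  check_edge_matrix(W)
  p <- nrow(W)
  labs <- rownames(W)
  len <- ifelse(W == 0, Inf, 1 / abs(W))
  diag(len) <- Inf

  d <- matrix(Inf, p, p, dimnames = list(labs, labs))
  sigma <- matrix(0, p, p, dimnames = list(labs, labs))
  for (s in seq_len(p)) {
    dist <- rep(Inf, p)
    cnt <- rep(0, p)
    dist[s] <- 0
    cnt[s] <- 1
    done <- rep(FALSE, p)
    repeat {
      u <- NA_integer_
      best <- Inf
      for (v in seq_len(p)) {
        if (!done[v] && dist[v] < best) {
          best <- dist[v]
          u <- v
        }
      }
      if (is.na(u)) break
      done[u] <- TRUE
      for (v in seq_len(p)) {
        if (done[v] || !is.finite(len[u, v])) next
        alt <- dist[u] + len[u, v]
        tol <- tie_tol * max(1, alt)
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          cnt[v] <- cnt[u]
        } else if (abs(alt - dist[v]) <= tol) {
          cnt[v] <- cnt[v] + cnt[u]
        }
      }
    }
    d[s, ] <- dist
    sigma[s, ] <- cnt
  }
  diag(d) <- 0
  diag(sigma) <- 0

  sigma_through <- array(
    0, dim = c(p, p, p),
    dimnames = list(through = labs, from = labs, to = labs)
  )
  for (i in seq_len(p)) {
    for (s in seq_len(p)) {
      for (t in seq_len(p)) {
        if (i == s || i == t || s == t) next
        if (!is.finite(d[s, t])) next
        via <- d[s, i] + d[i, t]
        if (is.finite(via) &&
            abs(via - d[s, t]) <= tie_tol * max(1, d[s, t])) {
          sigma_through[i, s, t] <- sigma[s, i] * sigma[i, t]
        }
      }
    }
  }
  structure(list(d = d, sigma = sigma, sigma_through = sigma_through),
            class = "shortest_path_table")
}

#' Closeness centrality
#'
#' `c_i = 1 / sum_j d(i, j)` over the shortest-path distances of
#' [shortest_paths()]. A node with any unreachable partner gets closeness 0
#' (documented convention for disconnected networks).
#'
#' @param paths a `shortest_path_table`.
#' @return Named numeric vector.
#' @export
closeness <- function(paths) {
  d <- paths$d
  p <- nrow(d)
  vapply(seq_len(p), function(i) {
    s <- sum(d[i, -i])
    if (!is.finite(s) || s == 0) 0 else 1 / s
  }, numeric(1)) |> setNames(rownames(d))
}

#' Betweenness centrality
#'
#' `b_i = sum over unordered pairs {s, t} (s != t != i) of
#' sigma_st(i) / sigma_st`, where pairs with no connecting path contribute
#' zero.
#'
#' @param paths a `shortest_path_table`.
#' @return Named numeric vector.
#' @export
betweenness <- function(paths) {
  sigma <- paths$sigma
  st <- paths$sigma_through
  p <- nrow(sigma)
  b <- numeric(p)
  for (i in seq_len(p)) {
    for (s in seq_len(p - 1)) {
      for (t in (s + 1):p) {
        if (s == i || t == i || sigma[s, t] == 0) next
        b[i] <- b[i] + st[i, s, t] / sigma[s, t]
      }
    }
  }
  setNames(b, rownames(sigma))
}

#' Cross-sectional centrality table
#'
#' Computes the four indices — strength, expected influence, closeness,
#' betweenness — raw and z-scored (sd denominator N-1; constant columns map
#' to zero z-scores, matching how standardized centrality profiles are
#' reported).
#'
#' @param W symmetric partial-correlation matrix, or a `ggm_fit`.
#' @return A `centrality_table` data frame with columns `node`, `index`,
#'   `raw`, `z`.
#' @export
centrality_table <- function(W) {
  if (inherits(W, "ggm_fit")) W <- W$W
  check_edge_matrix(W)
  paths <- shortest_paths(W)
  raw <- list(
    strength = net_strength(W),
    expected_influence = expected_influence(W),
    closeness = closeness(paths),
    betweenness = betweenness(paths)
  )
  out <- do.call(rbind, lapply(names(raw), function(ix) {
    data.frame(
      node = names(raw[[ix]]), index = ix,
      raw = unname(raw[[ix]]), z = unname(zscore(raw[[ix]]))
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Re-standardize a centrality table
#'
#' Recomputes the z column per index from the raw column (mean 0, sd 1 with
#' denominator N-1; constant indices map to zero).
#'
#' @param table a `centrality_table`.
#' @return The table with refreshed `z`.
#' @export
standardize_centrality <- function(table) {
  for (ix in unique(table$index)) {
    sel <- table$index == ix
    table$z[sel] <- zscore(table$raw[sel])
  }
  table
}
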