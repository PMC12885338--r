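# Internal helpers: scoped RNG, seed derivation, tiny provenance hash.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a master seed and a stream index, staying inside
# the 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 16807) %% 2147483647
}

# rolling polynomial hash of a character scalar, returned as 8 hex digits;
# used to stamp output manifests with a config fingerprint (not cryptographic)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

upper_tri_values <- function(M) M[upper.tri(M)]

# z-score with sd denominator n-1; constant columns map to zeros.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
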