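# Run expr with a local, seeded RNG state; the caller's RNG is untouched.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-item child seeds, kept inside 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483629)
}

# Piecewise-linear interpolation with constant extrapolation at both ends.
piecewise <- function(t, knots_t, knots_v) {
  stats::approx(knots_t, knots_v, xout = t, rule = 2)$y
}

# Largest-remainder apportionment of n into round(prop*n) integer counts.
largest_remainder <- function(n, prop) {
  raw <- prop * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}
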