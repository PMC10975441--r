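# Shared fixtures, all generated in code.

# Planted-signal design: y depends on exactly `k` informative bands that
# carry unit-scale variation; the remaining bands are pure noise at sd
# `noise`. Used to measure selection sensitivity.
planted_signal <- function(n = 60, p = 60, k = 3, noise = 0.005,
                           seed = 1, beta = c(1, -0.8, 0.6)) {
  set.seed(seed)
  x <- matrix(rnorm(n * p, 0, noise), n, p)
  informative <- sort(sample(p, k))
  x[, informative] <- matrix(rnorm(n * k), n, k)
  y <- drop(x[, informative] %*% beta[seq_len(k)]) + rnorm(n, 0, noise)
  list(x = x, y = y, informative = informative)
}

# small deterministic raw cube + references for calibration tests
tiny_cube <- function(nr = 4, nc = 5, nb = 3, wl = c(1000, 1100, 1200)) {
  dark <- array(100, dim = c(nr, nc, nb))
  white <- array(1100, dim = c(nr, nc, nb))
  list(dark = dark, white = white, wl = wl,
       make_raw = function(vals) hypercube(vals, wl, kind = "raw"))
}

# fast small-scale generator settings for property loops
fast_config <- function(seed, n_samples = 30, ...) {
  synthetic_config(n_samples = n_samples, n_bands = 64, seed = seed, ...)
}
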