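# Shared fixtures: all generated in code, nothing read from disk.

# A small valid spectrum set with an arbitrary intensity pattern.
tiny_set <- function(n_per_class = 2, p = 12, seed = 42, labels = 0:5) {
  grid <- wavelength_grid(seq(500, 900, length.out = p))
  n <- n_per_class * length(labels)
  X <- withr::with_seed(seed, matrix(stats::runif(n * p, 0.1, 2), n, p))
  lab <- rep(labels, each = n_per_class)
  spectrum_set(grid, X, lab, lab / 10)
}

# Planted-signal regression design: y depends on a few channels only.
planted_design <- function(n, p, channels, beta = 3, noise_sd = 0.05,
                           seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    y <- X[, channels, drop = FALSE] %*% rep_len(beta, length(channels)) +
      stats::rnorm(n, 0, noise_sd)
    list(X = X, y = as.numeric(y))
  })
}
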