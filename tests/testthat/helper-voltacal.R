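# Shared fixtures, generated in code.

# Small deterministic mixture set for calibration tests: n samples with
# uniform concentrations, default peaks/grid, fixed noise.
make_small_set <- function(n = 20, seed = 7, noise_sd = 0.05) {
  conc <- sample_random_concentrations(n, seed = seed)
  noise <- noise_model(noise_sd = noise_sd, seed = seed + 1)
  grid <- potential_grid()
  V <- sapply(seq_len(n), function(j) {
    s <- conc[, j]
    nm <- noise_model(noise$baseline_intercept, noise$baseline_slope,
                      noise_sd, seed = seed + j)
    simulate_voltammogram(s, grid = grid, noise = nm)$current
  })
  list(voltammograms = V, concentrations = conc[1:4, , drop = FALSE],
       grid = grid)
}

# Closed-form simple linear regression, independent of lm().
ols_oracle <- function(y, x) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  m <- sum((x - mx) * (y - my)) / sxx
  b <- my - m * mx
  res <- y - (b + m * x)
  s2 <- sum(res^2) / (n - 2)
  list(m = m, b = b, R = sum((x - mx) * (y - my)) /
         sqrt(sxx * sum((y - my)^2)),
       se_m = sqrt(s2 / sxx),
       se_b = sqrt(s2 * (1 / n + mx^2 / sxx)),
       sigma = sqrt(s2))
}
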