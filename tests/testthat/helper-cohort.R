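# Shared fixtures: small configs used across test files.

noise_free_config <- function(n_subjects = 2, n_periods = 2, seed = 7, ...) {
  simulation_config(
    n_subjects = n_subjects, n_periods = n_periods,
    jitter_meanlog = -Inf, enrichment_noise_cv = 0, turnover_noise_cv = 0,
    temp_coefficient = 0, seed = seed, ...
  )
}

# Brute-force OLS via the normal equations, independent of stats::lm.
brute_ols <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
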