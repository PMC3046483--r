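# fixtures shared across test files; everything is generated in code

# small deterministic series: values v[i, k, r] = 100*i + 10*k + r unless
# overridden, regulators = first m genes
tiny_series <- function(n = 3, n_times = 4, reps = 2, m = 2, values = NULL,
                        times = NULL) {
  if (is.null(times)) times <- seq(0, by = 3, length.out = n_times)
  if (is.null(values)) {
    values <- array(0, dim = c(n, n_times, reps))
    for (i in seq_len(n)) for (k in seq_len(n_times)) for (r in seq_len(reps))
      values[i, k, r] <- 100 * i + 10 * k + r
  }
  expression_series(values, times, gene_ids = paste0("g", seq_len(n)),
                    regulators = c(rep(TRUE, m), rep(FALSE, n - m)))
}

# a model-consistent noiseless series: latent path simulated from `model`,
# identical replicates
noiseless_series <- function(model, z0, times, reps = 2) {
  sim <- simulate_trajectory(model, z0, times, sigma_process = 0,
                             sigma_obs = 0, replicates = reps, seed = 1)
  sim$series
}

# sparse brownian model whose regulators rotate in pairs at two different
# frequencies (same-frequency pairs would be collinear sinusoids), so a long
# noiseless trajectory explores all regulator directions (identifiable design)
rotating_brownian_model <- function(n = 10, m = 5) {
  F <- matrix(0, n, m)
  F[1, 2] <- -0.2;  F[2, 1] <- 0.2
  F[3, 4] <- -0.45; F[4, 3] <- 0.45
  set.seed(7)
  for (i in (m + 1):n) {
    picks <- sample(m, 2)
    F[i, picks] <- round(stats::runif(2, -0.3, 0.3), 2)
  }
  b <- c(0, 0, 0, 0, 4, rep(1, n - m))
  dynamics_model(F, b, kind = "brownian")
}
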