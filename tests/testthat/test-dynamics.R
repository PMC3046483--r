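feedback_model <- function(coupling = 0.1)
  dynamics_model(matrix(c(0, coupling, coupling, 0), 2, 2), kind = "brownian")

test_that("one-step predictions match the discretized dynamics", {
  # symmetric positive feedback, first step: 100 -> 110 on both genes
  expect_equal(unname(predict_next(feedback_model(), c(100, 100), 1)),
               c(110, 110))
  # pure degradation: full decay step, then half step
  km3 <- dynamics_model(matrix(0, 1, 1), kind = "kinetic", tau = 3)
  expect_equal(predict_next(km3, 100, 3), 0, ignore_attr = TRUE)
  km6 <- dynamics_model(matrix(0, 1, 1), kind = "kinetic", tau = 6)
  expect_equal(predict_next(km6, 100, 3), 50, ignore_attr = TRUE)
  expect_error(predict_next(km3, c(1, 2), 3), "does not match")
  expect_error(predict_next(km3, 1, 0), "positive")
})

test_that("prediction is affine: linear in the state for zero bias", {
  set.seed(1)
  F <- matrix(rnorm(12, sd = 0.1), 4, 3)
  for (kind in c("kinetic", "brownian")) {
    mod <- dynamics_model(F, 0, kind = kind,
                          tau = if (kind == "kinetic") 5 else NULL)
    z <- rnorm(4); w <- rnorm(4)
    expect_equal(predict_next(mod, 2 * z + 3 * w, 2),
                 2 * predict_next(mod, z, 2) + 3 * predict_next(mod, w, 2))
  }
})

test_that("kinetic dynamics at delta_t = tau are brownian dynamics minus the state", {
  set.seed(2)
  F <- matrix(rnorm(6, sd = 0.1), 3, 2)
  b <- rnorm(3)
  kin <- dynamics_model(F, b, kind = "kinetic", tau = 3)
  bro <- dynamics_model(F, b, kind = "brownian")
  z <- runif(3, 50, 150)
  # full replacement: z + (F z + b - z) = (z + F z + b) - z
  expect_equal(predict_next(kin, z, 3), predict_next(bro, z, 1) - z)
})

test_that("the 10% feedback loop amplifies 100 to over 160 within 5 steps", {
  sim <- simulate_trajectory(feedback_model(), c(100, 100), times = 0:5)
  expect_equal(unname(sim$latent[, 6]), c(161.051, 161.051))
  expect_gt(sim$latent[1, 6], 160)
})

test_that("noiseless kinetic simulation follows the closed-form decay", {
  km <- dynamics_model(matrix(0, 2, 1), kind = "kinetic", tau = 9)
  sim <- simulate_trajectory(km, c(90, 30), times = seq(0, 12, by = 3))
  for (k in 0:4)
    expect_equal(unname(sim$latent[, k + 1]), c(90, 30) * (1 - 3 / 9)^k)
})

test_that("replicate mean converges to the latent path under observation noise", {
  km <- dynamics_model(matrix(0.1, 1, 1), kind = "kinetic", tau = 6)
  sim <- simulate_trajectory(km, 100, times = c(0, 3, 6), sigma_obs = 8,
                             replicates = 10000, seed = 42)
  mc_se <- 8 / sqrt(10000)
  dev <- abs(apply(sim$series$values, c(1, 2), mean) - sim$latent)
  expect_true(all(dev < 3 * mc_se))
})

test_that("simulation validates inputs and is seed-reproducible", {
  expect_error(simulate_trajectory(feedback_model(), c(1, 1), 0:2,
                                   sigma_obs = -1), ">= 0")
  a <- simulate_trajectory(feedback_model(), c(1, 1), 0:3, sigma_process = 2,
                           sigma_obs = 1, replicates = 2, seed = 99)
  b <- simulate_trajectory(feedback_model(), c(1, 1), 0:3, sigma_process = 2,
                           sigma_obs = 1, replicates = 2, seed = 99)
  expect_identical(a$latent, b$latent)
  expect_identical(a$series$values, b$series$values)
})

test_that("energy decomposes into gamma-weighted dynamic and observation parts", {
  # 1 gene, 2 time points, tau = delta_t, hand-set numbers:
  # y = (2, 4), z = (2, 3), F z + b = 5 at the source
  es <- tiny_series(n = 1, n_times = 2, reps = 1, m = 1,
                    values = array(c(2, 4), dim = c(1, 2, 1)),
                    times = c(0, 3))
  tr <- build_transition_sequences(es)
  mod <- dynamics_model(matrix(2, 1, 1), b = 1, kind = "kinetic", tau = 3)
  Z <- latents_from_observations(tr)
  Z$chains[[1]]$z_src[1, 1] <- 2
  Z$chains[[1]]$z_dst[1, 1] <- 3
  # response = (tau/dt)(3-2)+2 = 3; drive = 2*2+1 = 5; eta = -2
  # obs error = (2-2)^2 + (4-3)^2 = 1
  for (gam in c(0, 0.25, 1)) {
    e <- energy(tr, Z, mod, gam)
    expect_equal(e$dynamic_error, 4)
    expect_equal(e$observation_error, 1)
    expect_equal(e$total, gam * 4 + 1)
  }
  expect_error(energy(tr, Z, mod, -1), ">= 0")
})

test_that("model-consistent latents give zero energy; gamma 0 keeps only observation error", {
  mod <- feedback_model()
  es <- noiseless_series(mod, c(100, 100), 0:4)
  tr <- build_transition_sequences(es)
  Z <- latents_from_observations(tr)
  e <- energy(tr, Z, mod, 1)
  expect_equal(e$total, 0)
  # gamma 0: total is the observation error, minimized (to 0) by Z = Y
  wrong <- dynamics_model(matrix(c(0, 0.5, 0.5, 0), 2, 2), kind = "brownian")
  e0 <- energy(tr, Z, wrong, 0)
  expect_equal(e0$total, e0$observation_error)
  expect_equal(e0$total, 0)
})

test_that("energy is exactly quadratic in the latents", {
  set.seed(3)
  es <- tiny_series(n = 3, n_times = 4, reps = 2, m = 2)
  tr <- build_transition_sequences(es)
  mod <- dynamics_model(matrix(rnorm(6, sd = 0.2), 3, 2), b = rnorm(3),
                        kind = "kinetic", tau = 4)
  f_at <- function(x, base) {
    Z <- latents_from_observations(tr)
    Z$chains[[2]]$z_src[1, 2] <- base + x
    energy(tr, Z, mod, 0.7)$total
  }
  # for a quadratic the central second difference is exact at any step size,
  # so a large step avoids cancellation error entirely
  h <- 1
  hess <- function(base)
    (f_at(h, base) + f_at(-h, base) - 2 * f_at(0, base)) / h^2
  # numerical second derivative is the same constant at two distinct points
  expect_equal(hess(0), hess(37.5), tolerance = 1e-8)
})

test_that("model serialization round-trips through the text format", {
  set.seed(4)
  mod <- dynamics_model(matrix(rnorm(8), 4, 2), b = rnorm(4),
                        kind = "kinetic", tau = 3.5)
  prefix <- file.path(withr::local_tempdir(), "mod")
  write_model(mod, prefix)
  back <- read_model(prefix)
  expect_identical(back$F, mod$F)
  expect_identical(back$b, mod$b)
  expect_identical(back$tau, mod$tau)
  bro <- dynamics_model(matrix(1, 1, 1) * 0.1, kind = "brownian")
  write_model(bro, prefix)
  expect_identical(read_model(prefix)$kind, "brownian")
})

test_that("model construction rejects invalid parameters", {
  expect_error(dynamics_model(matrix(Inf, 1, 1), kind = "brownian"), "finite")
  expect_error(dynamics_model(matrix(0, 1, 1), kind = "kinetic"), "tau")
  expect_error(dynamics_model(matrix(0, 1, 1), kind = "kinetic", tau = -1),
               "tau")
  expect_error(dynamics_model(matrix(0, 1, 1), kind = "brownian", tau = 3),
               "not applicable")
  expect_error(dynamics_model(matrix(0, 1, 2), kind = "brownian"),
               "more regulator columns")
})
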