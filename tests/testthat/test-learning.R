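test_that("latent inference returns the observations exactly at gamma 0", {
  es <- tiny_series(n = 3, n_times = 5, reps = 2, m = 2)
  tr <- build_transition_sequences(es)
  mod <- dynamics_model(matrix(0.3, 3, 2), kind = "kinetic", tau = 3)
  Z <- infer_latents(tr, mod, gamma = 0)
  for (ci in seq_along(tr$chains)) {
    expect_identical(Z$chains[[ci]]$z_src, tr$chains[[ci]]$y_src)
    expect_identical(Z$chains[[ci]]$z_dst, tr$chains[[ci]]$y_dst)
  }
})

test_that("noiseless model-consistent observations are a stationary point of inference", {
  mod <- dynamics_model(matrix(c(0, 0.1, 0.1, 0), 2, 2), kind = "brownian")
  es <- noiseless_series(mod, c(100, 100), 0:4)
  tr <- build_transition_sequences(es)
  for (solver in c("exact", "descent")) {
    Z <- infer_latents(tr, mod, gamma = 0.5, solver = solver)
    expect_equal(Z$chains[[1]]$z_src, tr$chains[[1]]$y_src, tolerance = 1e-12)
    expect_equal(Z$chains[[1]]$z_dst, tr$chains[[1]]$y_dst, tolerance = 1e-12)
  }
})

test_that("inference solves the 1-gene quadratic exactly (hand normal equations)", {
  # 1 gene, 2 time points: unknowns (z_src, z_dst); energy =
  # gamma * ((tau/dt)(zd - zs) + zs - F zs - b)^2 + (zs - ys)^2 + (zd - yd)^2
  ys <- 2; yd <- 7; F <- 0.4; b <- 1.5; tau <- 6; dt <- 3; gam <- 0.8
  es <- tiny_series(n = 1, n_times = 2, reps = 1, m = 1,
                    values = array(c(ys, yd), dim = c(1, 2, 1)),
                    times = c(0, dt))
  tr <- build_transition_sequences(es)
  mod <- dynamics_model(matrix(F, 1, 1), b = b, kind = "kinetic", tau = tau)
  a <- tau / dt
  cs <- a - 1 + F        # residual = a zd - cs zs - b
  A <- matrix(c(gam * cs^2 + 1, -gam * a * cs,
                -gam * a * cs, gam * a^2 + 1), 2, 2)
  rhs <- c(ys - gam * cs * b, yd + gam * a * b)
  zstar <- solve(A, rhs)
  for (solver in c("exact", "descent")) {
    Z <- infer_latents(tr, mod, gamma = gam, solver = solver, tol = 1e-15,
                       max_iter = 5000)
    expect_equal(Z$chains[[1]]$z_src[1, 1], zstar[1], tolerance = 1e-6)
    expect_equal(Z$chains[[1]]$z_dst[1, 1], zstar[2], tolerance = 1e-6)
  }
})

test_that("descent and exact inference agree and never increase the energy", {
  set.seed(8)
  es <- tiny_series(n = 4, n_times = 5, reps = 2, m = 2,
                    values = array(runif(4 * 5 * 2, 10, 200), dim = c(4, 5, 2)))
  tr <- build_transition_sequences(es)
  mod <- dynamics_model(matrix(rnorm(8, sd = 0.2), 4, 2), b = rnorm(4, 5),
                        kind = "kinetic", tau = 4)
  Z0 <- latents_from_observations(tr)
  e0 <- energy(tr, Z0, mod, 0.6)$total
  Zd <- infer_latents(tr, mod, 0.6, solver = "descent", tol = 1e-14,
                      max_iter = 20000)
  Ze <- infer_latents(tr, mod, 0.6, solver = "exact")
  expect_lte(energy(tr, Zd, mod, 0.6)$total, e0)
  expect_equal(energy(tr, Zd, mod, 0.6)$total, energy(tr, Ze, mod, 0.6)$total,
               tolerance = 1e-9)
  for (ci in seq_along(tr$chains))
    expect_equal(Zd$chains[[ci]]$z_src, Ze$chains[[ci]]$z_src,
                 tolerance = 1e-5)
})

test_that("a fully penalized fit zeroes the influence row and keeps the mean", {
  set.seed(9)
  es <- tiny_series(n = 3, n_times = 5, reps = 2, m = 2,
                    values = array(runif(30, 10, 100), dim = c(3, 5, 2)))
  tr <- build_transition_sequences(es)
  Z <- latents_from_observations(tr)
  # lambda above the largest gradient at beta = 0 forces the null solution
  d <- ssmgrn:::stack_regression_rows(
    Z, tr, hyper_params(lambda = 1, kind = "kinetic", tau = 3))
  Xc <- scale(d$X, scale = FALSE)
  lam_max <- max(abs(crossprod(Xc, scale(d$Y, scale = FALSE)))) / nrow(d$X)
  h <- hyper_params(gamma = 0, tau = 3, lambda = 1.1 * lam_max,
                    method = "lars", kind = "kinetic")
  fit <- fit_dynamics(Z, tr, h)
  expect_true(all(fit$F == 0))
  expect_equal(fit$b, unname(colMeans(d$Y)))
})

test_that("near-unpenalized fits on identifiable noiseless data recover the truth", {
  mod <- rotating_brownian_model()   # 10 genes, 5 regulators
  set.seed(77)
  es <- noiseless_series(mod, runif(10, 50, 150), times = 0:20, reps = 2)
  tr <- build_transition_sequences(es)  # 4 chains x 20 = 80 rows
  Z <- latents_from_observations(tr)
  d <- ssmgrn:::stack_regression_rows(
    Z, tr, hyper_params(lambda = 0, kind = "brownian", tau = NULL))
  ols <- qr.coef(qr(cbind(1, d$X)), d$Y)  # independent least-squares oracle
  for (method in c("lars", "elasticnet", "gradient")) {
    h <- hyper_params(gamma = 0, tau = NULL, lambda = 1e-6, method = method,
                      kind = "brownian")
    fit <- fit_dynamics(Z, tr, h)
    expect_lt(max(abs(fit$F - mod$F)), 1e-4)
    expect_lt(max(abs(fit$F - t(ols[-1, ]))), 1e-4)
    expect_lt(max(abs(fit$b - ols[1, ])), 1e-4)
  }
})

test_that("lasso and elastic-net fits match the independent coordinate-descent oracle", {
  set.seed(10)
  es <- tiny_series(n = 6, n_times = 5, reps = 2, m = 4,
                    values = array(runif(60, 10, 300), dim = c(6, 5, 2)))
  tr <- build_transition_sequences(es)
  Z <- latents_from_observations(tr)
  for (method in c("lars", "elasticnet")) {
    h <- hyper_params(gamma = 0, tau = 3, lambda = 2, method = method,
                      kind = "kinetic")
    fit <- fit_dynamics(Z, tr, h)
    d <- ssmgrn:::stack_regression_rows(Z, tr, h)
    alpha <- if (method == "elasticnet") 0.5 else 1
    for (i in c(1, 4, 6)) {
      orac <- oracle_cd_penalized(d$X, d$Y[, i], lambda = 2, alpha = alpha)
      expect_equal(unname(fit$F[i, ]), orac$beta, tolerance = 1e-6)
      expect_equal(fit$b[i], orac$intercept, tolerance = 1e-6)
    }
  }
})

test_that("gradient (subgradient conjugate gradient) minimizes the same objective", {
  set.seed(11)
  X <- matrix(rnorm(30 * 4, sd = 10), 30, 4)
  y <- drop(X %*% c(0.5, 0, -0.3, 0)) + rnorm(30)
  for (lam in c(1e-4, 0.05)) {
    cg <- ssmgrn:::cg_l1_fit(X, y, lam)
    cd <- oracle_cd_penalized(X, y, lam, alpha = 1)
    expect_lt(max(abs(cg$beta - cd$beta)), 1e-4)
    expect_lt(abs(cg$intercept - cd$intercept), 1e-4)
  }
})

test_that("training with gamma 0 reduces to a direct fit on the observations", {
  set.seed(12)
  mod <- random_sparse_grn(6, 3, density = 0.3, seed = 13)
  ds <- synth_dataset(mod, seed = 14)
  tr <- build_transition_sequences(ds$series)
  Z <- latents_from_observations(tr)
  for (method in c("lars", "elasticnet", "gradient")) {
    h <- hyper_params(gamma = 0, tau = 3, lambda = 0.2, method = method,
                      epochs = 3, seed = 1)
    trained <- train_ssm(ds$series, h)
    direct <- fit_dynamics(Z, tr, h)
    expect_lt(max(abs(trained$model$F - direct$F)), 1e-8)
    expect_lt(max(abs(trained$model$b - direct$b)), 1e-8)
  }
})

test_that("the best epoch is the argmin of the dynamic-error log, first on ties", {
  mod <- random_sparse_grn(6, 3, density = 0.3, seed = 15)
  ds <- synth_dataset(mod, seed = 16)
  h <- hyper_params(gamma = 0.2, tau = 3, lambda = 0.5, epochs = 15, seed = 2)
  trained <- train_ssm(ds$series, h)
  expect_equal(trained$best_epoch,
               which(trained$per_epoch_dynamic_error ==
                       min(trained$per_epoch_dynamic_error))[1])
  # gamma 0 pins every epoch to the same fit: ties resolve to epoch 1
  h0 <- hyper_params(gamma = 0, tau = 3, lambda = 0.5, epochs = 5, seed = 2)
  expect_equal(train_ssm(ds$series, h0)$best_epoch, 1L)
})

test_that("identical seeds give bit-identical trained models", {
  mod <- random_sparse_grn(6, 3, density = 0.3, seed = 17)
  ds <- synth_dataset(mod, seed = 18)
  h <- hyper_params(gamma = 0.1, tau = 3, lambda = 0.5, epochs = 10, seed = 7)
  a <- train_ssm(ds$series, h)
  b <- train_ssm(ds$series, h)
  expect_identical(a$model$F, b$model$F)
  expect_identical(a$model$b, b$model$b)
  expect_identical(a$per_epoch_dynamic_error, b$per_epoch_dynamic_error)
  expect_identical(a$latents, b$latents)
  # different seeds differ (random initialization)
  h2 <- hyper_params(gamma = 0.1, tau = 3, lambda = 0.5, epochs = 10, seed = 8)
  expect_false(identical(train_ssm(ds$series, h2)$model$F, a$model$F))
})

test_that("alternation never increases the penalized energy, including on the non-uniform grid", {
  mod <- random_sparse_grn(8, 4, density = 0.25, seed = 19)
  ds <- synth_dataset(mod, seed = 20)   # grid 0,3,...,15,20: last step is 5 min
  gam <- 0.5; lam <- 0.8
  h <- hyper_params(gamma = gam, tau = 3, lambda = lam, epochs = 12, seed = 3)
  tr <- build_transition_sequences(ds$series)
  N <- length(tr$chains) * (ds$series$n_times - 1)
  set.seed(h$seed)
  gene_sd <- apply(ds$series$values, 1, sd)
  Z <- latents_from_observations(tr)
  Z$chains <- lapply(Z$chains, function(zc) {
    zc$z_src <- zc$z_src + matrix(rnorm(length(zc$z_src)), 8) * 0.01 * gene_sd
    zc$z_dst <- zc$z_dst + matrix(rnorm(length(zc$z_dst)), 8) * 0.01 * gene_sd
    zc
  })
  objective <- function(Z, model) {
    e <- energy(tr, Z, model, gam)
    e$total + gam * 2 * N * lam * sum(abs(model$F))
  }
  prev <- Inf
  warm <- NULL
  for (epoch in 1:12) {
    fitted <- fit_dynamics(Z, tr, h, warm_start = warm)
    warm <- fitted$F
    model <- dynamics_model(fitted$F, fitted$b, kind = "kinetic", tau = 3)
    Z <- infer_latents(tr, model, gam)
    cur <- objective(Z, model)
    expect_lte(cur, prev + 1e-9 * max(1, abs(prev)))
    prev <- cur
  }
})

test_that("sparsity at the penalized endpoint never exceeds the unpenalized fit", {
  mod <- random_sparse_grn(8, 4, density = 0.25, seed = 21)
  ds <- synth_dataset(mod, seed = 22)
  tr <- build_transition_sequences(ds$series)
  Z <- latents_from_observations(tr)
  fit0 <- fit_dynamics(Z, tr, hyper_params(gamma = 0, tau = 3, lambda = 0))
  fit_big <- fit_dynamics(Z, tr, hyper_params(gamma = 0, tau = 3, lambda = 1e7))
  expect_gte(sum(fit0$F != 0), sum(fit_big$F != 0))
  expect_true(all(fit_big$F == 0))
})

test_that("recovered influence signs approach the truth as observation noise vanishes", {
  agree <- 0; total <- 0
  for (s in 1:20) {
    mod <- random_sparse_grn(8, 4, density = 0.25, seed = 700 + s)
    ds <- synth_dataset(mod, sigma_process = 0, sigma_obs = 1e-6,
                        seed = 800 + s)
    h <- hyper_params(gamma = 0.1, tau = 3, lambda = 0.05, epochs = 40,
                      seed = s)
    trained <- train_ssm(ds$series, h)
    both <- trained$model$F != 0 & mod$F != 0
    agree <- agree + sum(sign(trained$model$F[both]) == sign(mod$F[both]))
    total <- total + sum(both)
  }
  expect_gt(total, 50)            # the fits do find the true edges
  expect_gt(agree / total, 0.97)  # and essentially always with the right sign
})

test_that("held-out sign prediction beats chance on low-noise synthetic data", {
  accs <- vapply(1:20, function(s) {
    mod <- random_sparse_grn(20, 10, density = 0.15, w_max = 0.3, tau = 3,
                             seed = 500 + s)
    ds <- synth_dataset(mod, sigma_obs_frac = 0.02, seed = 600 + s)
    ev <- evaluate_holdout(ds$series,
                           hyper_params(gamma = 0.1, tau = 3, lambda = 1,
                                        method = "lars", epochs = 100,
                                        seed = s))
    ev$pct_correct_all
  }, numeric(1))
  expect_gt(mean(accs), 60)
})

test_that("kinetic training demands tau and rejects bad hyper-parameters", {
  expect_error(hyper_params(gamma = -1), "gamma")
  expect_error(hyper_params(lambda = -1), "lambda")
  expect_error(hyper_params(epochs = 0), "epochs")
  expect_error(hyper_params(kind = "kinetic", tau = NULL), "tau")
  expect_error(hyper_params(kind = "kinetic", tau = NA), "tau")
  h <- hyper_params(kind = "brownian", tau = 3)  # tau dropped for brownian
  expect_null(h$tau)
})
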