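#' Hyper-parameters of the state-space learner
#'
#' Bundles the three tuned hyper-parameters — the state-space coefficient
#' `gamma` (weight of the dynamic error relative to the observation error;
#' `gamma = 0` collapses the model to a direct regression on the
#' observations), the kinetic time constant `tau`, and the L1 regularization
#' weight `lambda` — together with the optimizer, dynamics kind, epoch count
#' and seed.
#'
#' The penalized per-gene objective is
#' \deqn{\frac{1}{2N}\sum_k \eta_{ik}^2 + \lambda P(F_i),}
#' with `N` the number of stacked transitions and
#' \eqn{P(\beta) = \|\beta\|_1} for `method` `"lars"`/`"gradient"` and
#' \eqn{P(\beta) = \alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2}
#' (`alpha = enet_alpha`, default 0.5) for `"elasticnet"`. The bias is never
#' penalized.
#'
#' @param gamma state-space coefficient, >= 0.
#' @param tau kinetic time constant in minutes (kinetic kind only).
#' @param lambda L1 regularization weight, >= 0.
#' @param method optimizer for the learning step: `"lars"` (LASSO solution
#'   path), `"elasticnet"`, or `"gradient"` (subgradient conjugate gradient).
#' @param kind `"kinetic"` or `"brownian"` dynamics.
#' @param epochs number of alternating (learning, inference) epochs.
#' @param seed integer seed controlling latent and model initialization.
#' @param enet_alpha L1 share of the elastic-net penalty, in (0, 1].
#' @return list of class `ssm_hyper`.
#' @export
hyper_params <- function(gamma = 0.1, tau = 3, lambda = 0.1,
                         method = c("lars", "elasticnet", "gradient"),
                         kind = c("kinetic", "brownian"),
                         epochs = 100, seed = 1, enet_alpha = 0.5) {
  method <- match.arg(method)
  kind <- match.arg(kind)
  if (!is.numeric(gamma) || gamma < 0) stop("`gamma` must be >= 0")
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (kind == "kinetic" &&
      (is.null(tau) || is.na(tau) || !is.numeric(tau) || tau <= 0))
    stop("kinetic dynamics require tau > 0")
  if (kind == "brownian") tau <- NULL
  if (enet_alpha <= 0 || enet_alpha > 1) stop("`enet_alpha` must be in (0, 1]")
  structure(list(gamma = gamma, tau = tau, lambda = lambda, method = method,
                 kind = kind, epochs = as.integer(epochs),
                 seed = as.integer(seed), enet_alpha = enet_alpha),
            class = "ssm_hyper")
}

#' @export
print.ssm_hyper <- function(x, ...) {
  cat(sprintf("ssm_hyper: %s/%s, gamma = %g, tau = %s, lambda = %g, %d epochs, seed %d\n",
              x$kind, x$method, x$gamma,
              if (is.null(x$tau)) "NA" else format(x$tau), x$lambda,
              x$epochs, x$seed))
  invisible(x)
}

#' Latent trajectories equal to the observations
#'
#' The starting point (and, at `gamma = 0`, the exact minimizer) of latent
#' inference: every latent state equals its observed value.
#'
#' @param transitions an [build_transition_sequences()] object.
#' @return object of class `ssm_latents`: per chain, matrices `z_src` and
#'   `z_dst` aligned with the chain's observation pairs.
#' @export
latents_from_observations <- function(transitions) {
  stopifnot(inherits(transitions, "ssm_transitions"))
  chains <- lapply(transitions$chains, function(ch)
    list(z_src = ch$y_src, z_dst = ch$y_dst))
  structure(list(chains = chains, times = transitions$times,
                 n = transitions$n),
            class = "ssm_latents")
}

#' Infer latent expression trajectories
#'
#' Inference step of the alternating algorithm: minimizes the energy
#' [energy()] with respect to the latent states, the model being held fixed.
#' Because the energy is an (strictly convex) quadratic in the latents, the
#' default solver computes the exact minimizer by a per-transition linear
#' solve; `solver = "descent"` runs gradient descent with exact line search
#' in the latent space and reaches the same minimizer, stopping when the
#' relative energy decrease over one pass falls below `tol`.
#'
#' With `gamma = 0` the observation term alone is minimized and the latents
#' equal the observations exactly.
#'
#' @param transitions an [build_transition_sequences()] object.
#' @param model an [dynamics_model()] object, fixed during the call.
#' @param gamma state-space coefficient, >= 0.
#' @param tol relative-decrease convergence threshold (descent solver).
#' @param max_iter iteration cap (descent solver).
#' @param solver `"exact"` or `"descent"`.
#' @return object of class `ssm_latents`.
#' @export
infer_latents <- function(transitions, model, gamma, tol = 1e-12,
                          max_iter = 1000, solver = c("exact", "descent")) {
  stopifnot(inherits(transitions, "ssm_transitions"),
            inherits(model, "ssm_model"))
  solver <- match.arg(solver)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("`gamma` must be a single number >= 0")
  if (gamma == 0) return(latents_from_observations(transitions))
  if (solver == "exact") {
    infer_latents_exact(transitions, model, gamma)
  } else {
    infer_latents_descent(transitions, model, gamma, tol, max_iter)
  }
}

# per-transition operator: residual = a * z_dst - B %*% z_src - b
transition_operator <- function(model, dt) {
  n <- model$n
  G <- matrix(0, n, n)
  G[, seq_len(model$m)] <- model$F
  if (model$kind == "kinetic") {
    a <- model$tau / dt
    B <- diag(a - 1, n) + G
  } else {
    a <- 1
    B <- diag(1, n) + G
  }
  list(a = a, B = B)
}

infer_latents_exact <- function(transitions, model, gamma) {
  n <- transitions$n
  dts <- transitions$delta_t
  # factor one system per transition index; dt pattern is shared by chains
  solvers <- lapply(dts, function(dt) {
    op <- transition_operator(model, dt)
    gt <- gamma / (1 + gamma * op$a^2)
    M <- diag(1, n) + gt * crossprod(op$B)
    list(a = op$a, B = op$B, gt = gt, chol = chol(M))
  })
  chains <- lapply(transitions$chains, function(ch) {
    z_src <- ch$y_src
    z_dst <- ch$y_dst
    for (k in seq_along(dts)) {
      s <- solvers[[k]]
      rhs <- ch$y_src[, k] + s$gt * crossprod(s$B, s$a * ch$y_dst[, k] - model$b)
      zs <- backsolve(s$chol, forwardsolve(t(s$chol), rhs))
      zd <- (ch$y_dst[, k] + gamma * s$a * (s$B %*% zs + model$b)) /
        (1 + gamma * s$a^2)
      z_src[, k] <- zs
      z_dst[, k] <- zd
    }
    list(z_src = z_src, z_dst = z_dst)
  })
  structure(list(chains = chains, times = transitions$times, n = n),
            class = "ssm_latents")
}

infer_latents_descent <- function(transitions, model, gamma, tol, max_iter) {
  n <- transitions$n
  dts <- transitions$delta_t
  ops <- lapply(dts, transition_operator, model = model)
  Z <- latents_from_observations(transitions)

  energy_of <- function(Z) energy(transitions, Z, model, gamma)$total
  gradient_of <- function(Z) {
    lapply(seq_along(Z$chains), function(ci) {
      ch <- transitions$chains[[ci]]
      zc <- Z$chains[[ci]]
      gs <- zc$z_src
      gd <- zc$z_dst
      for (k in seq_along(dts)) {
        op <- ops[[k]]
        r <- op$a * zc$z_dst[, k] - op$B %*% zc$z_src[, k] - model$b
        gs[, k] <- -2 * gamma * crossprod(op$B, r) +
          2 * (zc$z_src[, k] - ch$y_src[, k])
        gd[, k] <- 2 * gamma * op$a * r + 2 * (zc$z_dst[, k] - ch$y_dst[, k])
      }
      list(z_src = gs, z_dst = gd)
    })
  }
  add_scaled <- function(Z, D, alpha) {
    Z$chains <- lapply(seq_along(Z$chains), function(ci)
      list(z_src = Z$chains[[ci]]$z_src + alpha * D[[ci]]$z_src,
           z_dst = Z$chains[[ci]]$z_dst + alpha * D[[ci]]$z_dst))
    Z
  }
  dot <- function(A, B) {
    sum(vapply(seq_along(A), function(ci)
      sum(A[[ci]]$z_src * B[[ci]]$z_src) + sum(A[[ci]]$z_dst * B[[ci]]$z_dst),
      numeric(1)))
  }

  e <- energy_of(Z)
  for (it in seq_len(max_iter)) {
    g <- gradient_of(Z)
    gg <- dot(g, g)
    if (gg == 0) break
    d <- lapply(g, function(x) list(z_src = -x$z_src, z_dst = -x$z_dst))
    # exact line search on the quadratic: curvature from the affine gradient
    g_at <- gradient_of(add_scaled(Z, d, 1))
    hd <- dot(lapply(seq_along(g), function(ci)
      list(z_src = g_at[[ci]]$z_src - g[[ci]]$z_src,
           z_dst = g_at[[ci]]$z_dst - g[[ci]]$z_dst)), d)
    if (!is.finite(hd) || hd <= 0)
      stop("non-finite curvature during latent descent at iteration ", it)
    alpha <- gg / hd
    Z <- add_scaled(Z, d, alpha)
    e_new <- energy_of(Z)
    if (!is.finite(e_new))
      stop("non-finite energy during latent descent at iteration ", it)
    if (e - e_new <= tol * max(e, 1)) {
      e <- e_new
      break
    }
    e <- e_new
  }
  Z
}

#' Sparse fit of the influence matrix and bias
#'
#' Learning step of the alternating algorithm: for every target gene i, the
#' gene's dynamic response (kinetic:
#' \eqn{\frac{\tau}{\Delta t}(z_i(t_{k+1}) - z_i(t_k)) + z_i(t_k)};
#' brownian: \eqn{z_i(t_{k+1}) - z_i(t_k)}) is regressed on the regulator
#' latents \eqn{z_{1..m}(t_k)} with an unpenalized intercept `b_i`, under the
#' penalty defined by `hyper` (see [hyper_params()]). All transitions of all
#' chains are stacked as regression rows; the per-gene problems are
#' independent.
#'
#' LASSO and elastic-net solutions are computed by covariance-update
#' coordinate descent, vectorized across target genes (which share the
#' design matrix); `method = "gradient"` minimizes the same objective by
#' Polak-Ribiere conjugate gradient with backtracking line search, handling
#' the L1 term by subgradient.
#'
#' @param latents an `ssm_latents` object aligned with `transitions`.
#' @param transitions an [build_transition_sequences()] object.
#' @param hyper an [hyper_params()] object.
#' @param warm_start optional `n x m` matrix used as the coordinate-descent
#'   starting point (the objective is convex, so this affects speed only;
#'   [train_ssm()] passes the previous epoch's fit).
#' @return list with the fitted `n x m` matrix `F` and length-`n` bias `b`.
#' @export
fit_dynamics <- function(latents, transitions, hyper, warm_start = NULL) {
  stopifnot(inherits(latents, "ssm_latents"),
            inherits(transitions, "ssm_transitions"),
            inherits(hyper, "ssm_hyper"))
  check_latents_aligned(latents, transitions)
  if (hyper$lambda < 0) stop("`lambda` must be >= 0")
  design <- stack_regression_rows(latents, transitions, hyper)
  X <- design$X
  Y <- design$Y
  if (nrow(X) < 1L) stop("no regression rows: need at least one transition")

  n <- transitions$n
  m <- transitions$m
  alpha <- if (hyper$method == "elasticnet") hyper$enet_alpha else 1
  dn <- list(transitions$gene_ids, transitions$gene_ids[seq_len(m)])
  if (hyper$method == "gradient") {
    F_hat <- matrix(0, n, m, dimnames = dn)
    b_hat <- numeric(n)
    for (i in seq_len(n)) {
      fit <- cg_l1_fit(X, Y[, i], hyper$lambda)
      F_hat[i, ] <- fit$beta
      b_hat[i] <- fit$intercept
    }
  } else {
    fit <- cd_penalized_multi(X, Y, lambda = hyper$lambda, alpha = alpha,
                              B0 = if (!is.null(warm_start)) t(warm_start))
    F_hat <- t(fit$B)
    dimnames(F_hat) <- dn
    b_hat <- fit$intercept
  }
  list(F = F_hat, b = b_hat)
}

# stack all (chain, transition) rows: X holds regulator latents at the
# source, Y the per-gene dynamic responses
stack_regression_rows <- function(latents, transitions, hyper) {
  model_stub <- list(kind = hyper$kind, tau = hyper$tau)
  m <- transitions$m
  Xs <- list()
  Ys <- list()
  for (ci in seq_along(transitions$chains)) {
    zc <- latents$chains[[ci]]
    resp <- if (hyper$kind == "kinetic") {
      scale <- rep(hyper$tau / transitions$delta_t, each = transitions$n)
      (zc$z_dst - zc$z_src) * scale + zc$z_src
    } else {
      zc$z_dst - zc$z_src
    }
    Xs[[ci]] <- t(zc$z_src[seq_len(m), , drop = FALSE])
    Ys[[ci]] <- t(resp)
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

# Penalized least squares for all target genes at once. Objective per gene:
# (1/2N)||y - b - X beta||^2 + lambda (alpha |beta|_1 + (1-alpha)/2
# |beta|_2^2), unstandardized predictors, unpenalized intercept. After
# centering out the intercept, each gene's problem is
# (1/2) beta' Q beta - q' beta + thr |beta|_1 with Q = X'X/N + lambda(1-alpha) I,
# q = X'y/N, thr = lambda * alpha, solved exactly by active-set feature-sign
# search (falling back to cyclic coordinate descent in degenerate cases).
cd_penalized_multi <- function(X, Y, lambda, alpha, B0 = NULL) {
  N <- nrow(X)
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx)
  Yc <- sweep(Y, 2L, my)
  if (lambda == 0) {
    B <- qr.coef(qr(Xc), Yc)
    B[is.na(B)] <- 0
    B <- matrix(B, ncol(X), ncol(Y))
  } else {
    C <- crossprod(Xc) / N        # m x m
    D <- crossprod(Xc, Yc) / N    # m x n
    m <- ncol(X)
    ng <- ncol(Y)
    Q <- C + diag(lambda * (1 - alpha), m)
    thr <- lambda * alpha
    B <- matrix(0, m, ng)
    for (i in seq_len(ng)) {
      beta0 <- if (is.null(B0)) numeric(m) else B0[, i]
      beta <- feature_sign_search(Q, D[, i], thr, beta0)
      if (is.null(beta) && any(beta0 != 0))   # cold restart before giving up
        beta <- feature_sign_search(Q, D[, i], thr, numeric(m))
      if (is.null(beta)) beta <- cd_cyclic_single(Q, D[, i], thr, beta0)
      B[, i] <- beta
    }
  }
  list(B = B, intercept = as.numeric(my - crossprod(B, mx)))
}

# exact minimizer of (1/2) b'Qb - q'b + thr |b|_1 (Lee et al. feature-sign
# search); returns NULL if an active-set system is singular
feature_sign_search <- function(Q, q, thr, beta0, max_steps = 10000L) {
  m <- length(q)
  beta <- beta0
  eps <- 1e-10 * max(thr, abs(q), 1)
  objective <- function(b)
    0.5 * sum(b * (Q %*% b)) - sum(q * b) + thr * sum(abs(b))
  prev_obj <- objective(beta)
  for (step in seq_len(max_steps)) {
    g <- as.numeric(Q %*% beta - q)
    active <- beta != 0
    # optimality: active coords have exact subgradient zero, inactive within thr
    stat_active <- !any(active) ||
      max(abs(g[active] + thr * sign(beta[active]))) <= eps
    worst <- if (all(active)) -Inf else max(abs(g[!active])) - thr
    if (stat_active && worst <= eps) return(beta)
    if (stat_active) {
      # current active set is optimal: activate the worst KKT violator
      j <- which(!active)[which.max(abs(g[!active]))]
      active[j] <- TRUE
      theta_j <- -sign(g[j])
    } else {
      # re-optimize the current active set first (e.g. from a warm start)
      theta_j <- NULL
    }
    A <- which(active)
    theta <- sign(beta[A])
    if (!is.null(theta_j)) theta[match(j, A)] <- theta_j
    # inner loop: exact solve under fixed signs, stepping through zero
    # crossings until signs are consistent
    repeat {
      bnew <- tryCatch(solve(Q[A, A, drop = FALSE], q[A] - thr * theta),
                       error = function(e) NULL)
      if (is.null(bnew)) return(NULL)
      if (all(sign(bnew) == theta)) {
        beta[] <- 0
        beta[A] <- bnew
        break
      }
      # discrete line search over the zero crossings on [beta_A, bnew]
      bold <- beta[A]
      cross <- which(sign(bnew) != theta)
      tvals <- bold[cross] / (bold[cross] - bnew[cross])
      tvals <- unique(pmin(tvals[tvals > 0], 1))
      if (!length(tvals)) return(NULL)  # degenerate: no strict progress
      best_obj <- Inf
      best_b <- NULL
      for (tv in tvals) {
        cand <- bold + tv * (bnew - bold)
        cand[abs(cand) <= 1e-14 * max(abs(cand), 1)] <- 0
        full <- numeric(m)
        full[A] <- cand
        o <- objective(full)
        if (o < best_obj) {
          best_obj <- o
          best_b <- cand
        }
      }
      if (is.null(best_b)) return(NULL)
      beta[] <- 0
      beta[A] <- best_b
      keep <- best_b != 0
      if (!any(keep)) break
      A <- A[keep]
      theta <- sign(best_b[keep])
    }
    # near-singular systems can cycle: demand strict progress per outer step
    cur_obj <- objective(beta)
    if (cur_obj > prev_obj - 1e-14 * max(1, abs(prev_obj))) {
      g <- as.numeric(Q %*% beta - q)
      active <- beta != 0
      stat_active <- !any(active) ||
        max(abs(g[active] + thr * sign(beta[active]))) <= eps
      worst <- if (all(active)) -Inf else max(abs(g[!active])) - thr
      if (stat_active && worst <= eps) return(beta)
      return(NULL)
    }
    prev_obj <- cur_obj
  }
  NULL
}

# safeguarded cyclic coordinate descent on the same per-gene objective;
# bounded fallback for the degenerate systems feature-sign search declines
cd_cyclic_single <- function(Q, q, thr, beta0, tol = 1e-14,
                             max_sweeps = 10000L) {
  m <- length(q)
  beta <- beta0
  scale_ref <- max(abs(q), 1)
  for (sweep_i in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (Q[j, j] == 0) next
      r <- q[j] - sum(Q[j, ] * beta) + Q[j, j] * beta[j]
      bj <- sign(r) * max(abs(r) - thr, 0) / Q[j, j]
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta <= tol * scale_ref) break
  }
  beta
}

# subgradient Polak-Ribiere conjugate gradient with backtracking, on
# (1/2N)||y - b - X beta||^2 + lambda |beta|_1; warm start at least squares
cg_l1_fit <- function(X, y, lambda, max_iter = 2000, tol = 1e-14) {
  N <- nrow(X)
  A <- cbind(1, X)
  p <- ncol(A)
  theta <- {
    cf <- qr.coef(qr(A), y)
    cf[is.na(cf)] <- 0
    cf
  }
  objective <- function(th) {
    r <- y - A %*% th
    sum(r * r) / (2 * N) + lambda * sum(abs(th[-1L]))
  }
  subgradient <- function(th) {
    gs <- -crossprod(A, y - A %*% th) / N
    g <- as.numeric(gs)
    for (j in 2:p) {
      if (th[j] != 0) {
        g[j] <- g[j] + lambda * sign(th[j])
      } else {
        g[j] <- sign(g[j]) * max(0, abs(g[j]) - lambda)
      }
    }
    g
  }
  f <- objective(theta)
  g <- subgradient(theta)
  d <- -g
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(g * g))
    if (gnorm < 1e-13 * max(1, abs(f))) break
    if (sum(g * d) >= 0 || it %% (p + 1L) == 0L) d <- -g
    # backtracking Armijo line search
    step <- 1
    f_new <- f
    theta_new <- theta
    repeat {
      cand <- theta + step * d
      fc <- objective(cand)
      if (fc <= f + 1e-4 * step * sum(g * d)) {
        theta_new <- cand
        f_new <- fc
        break
      }
      step <- step / 2
      if (step < 1e-16) break
    }
    if (f - f_new <= tol * max(1, abs(f))) {
      theta <- theta_new
      break
    }
    g_new <- subgradient(theta_new)
    beta_pr <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    d <- -g_new + beta_pr * d
    theta <- theta_new
    g <- g_new
    f <- f_new
  }
  list(intercept = theta[1L], beta = theta[-1L])
}

#' Train the noise-reducing state-space model
#'
#' Runs the full alternating procedure: latents are initialized at the
#' observations plus a small seeded Gaussian perturbation (1% of each gene's
#' observed standard deviation) and the influence matrix at small seeded
#' Gaussian values; each epoch then performs one learning step
#' ([fit_dynamics()]) followed by one inference step ([infer_latents()], run
#' to its exact minimizer). The dynamic error is logged per epoch and the
#' returned model is the snapshot from the epoch where it is minimal (first
#' epoch on ties).
#'
#' With `gamma = 0` the latents are pinned at the observations (no
#' initialization noise: the observation term alone determines them), so the
#' result equals a single direct sparse regression on the raw data.
#'
#' @param series an [expression_series()] object.
#' @param hyper an [hyper_params()] object.
#' @return object of class `ssm_trained`: `model` (the best-epoch
#'   [dynamics_model()]), `latents` (best-epoch latent trajectories),
#'   `per_epoch_dynamic_error`, `best_epoch`, `hyper`, and the training
#'   `transitions`.
#' @export
train_ssm <- function(series, hyper) {
  stopifnot(inherits(series, "ssm_series"), inherits(hyper, "ssm_hyper"))
  if (hyper$kind == "kinetic" && is.null(hyper$tau))
    stop("kinetic dynamics require tau")
  transitions <- build_transition_sequences(series)
  n <- transitions$n
  m <- transitions$m
  set.seed(hyper$seed)

  if (hyper$gamma == 0) {
    Z <- latents_from_observations(transitions)
  } else {
    gene_sd <- apply(series$values, 1L, stats::sd)
    sigma_init <- 0.01 * gene_sd
    Z <- latents_from_observations(transitions)
    Z$chains <- lapply(Z$chains, function(zc) {
      zc$z_src <- zc$z_src + matrix(stats::rnorm(length(zc$z_src)),
                                    n) * sigma_init
      zc$z_dst <- zc$z_dst + matrix(stats::rnorm(length(zc$z_dst)),
                                    n) * sigma_init
      zc
    })
  }
  # F is refitted before first use; small random values keep runs distinct
  F_cur <- matrix(stats::rnorm(n * m, sd = 0.01), n, m)

  dyn_log <- numeric(hyper$epochs)
  best <- NULL
  warm <- NULL
  for (epoch in seq_len(hyper$epochs)) {
    fitted <- fit_dynamics(Z, transitions, hyper, warm_start = warm)
    warm <- fitted$F
    model <- dynamics_model(fitted$F, fitted$b, kind = hyper$kind,
                            tau = hyper$tau)
    Z <- infer_latents(transitions, model, hyper$gamma)
    e <- energy(transitions, Z, model, hyper$gamma)
    dyn_log[epoch] <- e$dynamic_error
    if (is.null(best) || e$dynamic_error < best$dynamic_error) {
      best <- list(model = model, latents = Z, epoch = epoch,
                   dynamic_error = e$dynamic_error)
    }
  }
  structure(list(model = best$model, latents = best$latents,
                 per_epoch_dynamic_error = dyn_log, best_epoch = best$epoch,
                 hyper = hyper, transitions = transitions),
            class = "ssm_trained")
}

#' @export
print.ssm_trained <- function(x, ...) {
  cat(sprintf(
    "ssm_trained: %s/%s, best epoch %d/%d (dynamic error %.6g), F %d x %d\n",
    x$hyper$kind, x$hyper$method, x$best_epoch, x$hyper$epochs,
    x$per_epoch_dynamic_error[x$best_epoch], x$model$n, x$model$m))
  invisible(x)
}

#' Average latent state at one time point
#'
#' Latent trajectories are estimated per transition role (source at t_k,
#' destination at t_{k+1}) for every replicate chain; this collapses them to
#' a single state vector at a grid index by averaging all roles that cover
#' that time across chains.
#'
#' @param latents an `ssm_latents` object (or an `ssm_trained`, whose
#'   best-epoch latents are used).
#' @param time_index index into the training grid, 1-based.
#' @return numeric vector of length `n`.
#' @export
latent_at_time <- function(latents, time_index) {
  if (inherits(latents, "ssm_trained")) latents <- latents$latents
  stopifnot(inherits(latents, "ssm_latents"))
  T_ <- length(latents$times)
  if (time_index < 1L || time_index > T_)
    stop("`time_index` outside the latent grid")
  acc <- numeric(latents$n)
  cnt <- 0L
  for (zc in latents$chains) {
    if (time_index <= T_ - 1L) {
      acc <- acc + zc$z_src[, time_index]
      cnt <- cnt + 1L
    }
    if (time_index >= 2L) {
      acc <- acc + zc$z_dst[, time_index - 1L]
      cnt <- cnt + 1L
    }
  }
  acc / cnt
}
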