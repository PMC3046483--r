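#' Linear regulatory dynamics model
#'
#' The learned object of the state-space model: an `n x m` influence matrix
#' `F` (signed linear effect of regulator j on gene i), a per-gene bias `b`,
#' and the dynamics kind. The discretized kinetic model advances expression
#' by
#' \deqn{z_{k+1,i} = z_{k,i} + \frac{\Delta t}{\tau}\Big(\sum_j F_{ij} z_{k,j} + b_i - z_{k,i}\Big),}
#' i.e. first-order mRNA decay with time constant `tau` towards a level set
#' by the regulators. "Brownian motion" dynamics drop the degradation term
#' and model changes directly: \eqn{z_{k+1} = z_k + F z_k + b} (unit time
#' scale, `tau` not applicable).
#'
#' Regulators are assumed to occupy state indices `1..m`, matching the
#' canonical gene ordering of [expression_series()].
#'
#' @param F numeric `n x m` influence matrix with finite entries. Row names
#'   are gene ids, column names regulator ids (defaults are generated).
#' @param b numeric bias vector of length `n` (recycled from a scalar).
#' @param kind `"kinetic"` (with degradation) or `"brownian"`.
#' @param tau kinetic time constant in minutes (> 0); required for
#'   `kind = "kinetic"`, must be omitted for `"brownian"`.
#' @return An object of class `ssm_model`.
#' @examples
#' feedback <- dynamics_model(matrix(c(0, 0.1, 0.1, 0), 2, 2),
#'                            kind = "brownian")
#' predict_next(feedback, c(100, 100), delta_t = 1)  # c(110, 110)
#' @export
dynamics_model <- function(F, b = 0, kind = c("kinetic", "brownian"),
                           tau = NULL) {
  kind <- match.arg(kind)
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("`F` must have finite entries")
  n <- nrow(F)
  m <- ncol(F)
  if (m > n) stop("more regulator columns than genes")
  b <- rep_len(as.numeric(b), n)
  if (!all(is.finite(b))) stop("`b` must be finite")
  if (kind == "kinetic") {
    if (is.null(tau) || !is.numeric(tau) || length(tau) != 1L || tau <= 0)
      stop("kinetic dynamics require a single tau > 0")
    tau <- as.numeric(tau)
  } else {
    if (!is.null(tau)) stop("tau is not applicable to brownian dynamics")
    tau <- NULL
  }
  if (is.null(rownames(F))) rownames(F) <- paste0("g", seq_len(n))
  if (is.null(colnames(F))) colnames(F) <- rownames(F)[seq_len(m)]
  structure(list(kind = kind, F = F, b = b, tau = tau,
                 n = n, m = m),
            class = "ssm_model")
}

#' @export
print.ssm_model <- function(x, ...) {
  cat(sprintf("ssm_model (%s%s): F is %d x %d, %d nonzero entries\n",
              x$kind,
              if (x$kind == "kinetic") paste0(", tau = ", x$tau) else "",
              x$n, x$m, sum(x$F != 0)))
  invisible(x)
}

#' One-step prediction of the dynamics
#'
#' Advances a state vector by one transition of length `delta_t`. See
#' [dynamics_model()] for the update equations. With `F = 0`, `b = 0` the
#' kinetic model is pure decay: `z * (1 - delta_t / tau)`.
#'
#' @param model an [dynamics_model()] object.
#' @param z numeric state vector of length `n` (regulators first), or an
#'   `n x k` matrix of states advanced column-wise.
#' @param delta_t transition length in minutes (> 0). Ignored by brownian
#'   dynamics, which are defined on the unit step.
#' @return predicted state(s), same shape as `z`.
#' @export
predict_next <- function(model, z, delta_t = 1) {
  stopifnot(inherits(model, "ssm_model"))
  was_vector <- !is.matrix(z)
  z <- as.matrix(z)
  if (nrow(z) != model$n)
    stop("state dimension ", nrow(z), " does not match model n = ", model$n)
  if (!all(is.finite(z))) stop("`z` must be finite")
  if (!is.numeric(delta_t) || length(delta_t) != 1L || delta_t <= 0)
    stop("`delta_t` must be a single positive number")
  drive <- model$F %*% z[seq_len(model$m), , drop = FALSE] + model$b
  out <- if (model$kind == "kinetic") {
    z + (delta_t / model$tau) * (drive - z)
  } else {
    z + drive
  }
  if (was_vector) drop(out) else out
}

#' Energy of a latent assignment under the state-space model
#'
#' The objective minimized during latent inference:
#' \deqn{e_\gamma = \gamma \sum \eta^2 + \sum \epsilon^2,}
#' where the dynamic residuals \eqn{\eta} measure how far each latent
#' transition deviates from the model and the observation residuals
#' \eqn{\epsilon = y - z} tie latents to the data (the observation model is
#' the identity). Dynamic residuals are measured on the regression response
#' scale, \eqn{\eta_i = \frac{\tau}{\Delta t}(z^{dst}_i - z^{src}_i) +
#' z^{src}_i - (F z^{src})_i - b_i} for kinetic dynamics and
#' \eqn{z^{dst} - z^{src} - F z^{src} - b} for brownian, so the inference and
#' learning steps minimize the same quadratic form on any grid; when
#' \eqn{\tau = \Delta t} this coincides with the one-step prediction residual
#' \eqn{z^{dst} - \hat z^{dst}}.
#'
#' @param transitions an [build_transition_sequences()] object.
#' @param latents an `ssm_latents` object aligned with `transitions` (see
#'   [infer_latents()]).
#' @param model an [dynamics_model()] object.
#' @param gamma state-space coefficient (>= 0) weighting the dynamic error.
#' @return list of class `ssm_energy` with `dynamic_error`,
#'   `observation_error`, `gamma`, and `total = gamma * dynamic_error +
#'   observation_error`.
#' @export
energy <- function(transitions, latents, model, gamma) {
  stopifnot(inherits(transitions, "ssm_transitions"),
            inherits(latents, "ssm_latents"),
            inherits(model, "ssm_model"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("`gamma` must be a single number >= 0")
  check_latents_aligned(latents, transitions)
  if (model$n != transitions$n || model$m != transitions$m)
    stop("model dimensions do not match the transition set")

  dyn <- 0
  obs <- 0
  for (ci in seq_along(transitions$chains)) {
    ch <- transitions$chains[[ci]]
    zc <- latents$chains[[ci]]
    r <- dynamic_residuals(model, zc$z_src, zc$z_dst, transitions$delta_t)
    dyn <- dyn + sum(r * r)
    obs <- obs + sum((ch$y_src - zc$z_src)^2) + sum((ch$y_dst - zc$z_dst)^2)
  }
  structure(list(dynamic_error = dyn, observation_error = obs,
                 gamma = gamma, total = gamma * dyn + obs),
            class = "ssm_energy")
}

#' @export
print.ssm_energy <- function(x, ...) {
  cat(sprintf("e_gamma: %.6g = %.3g * %.6g (dynamic) + %.6g (observation)\n",
              x$total, x$gamma, x$dynamic_error, x$observation_error))
  invisible(x)
}

# response-scale dynamic residuals for all transitions of one chain:
# columns are transitions, delta_t recycled per column
dynamic_residuals <- function(model, z_src, z_dst, delta_t) {
  drive <- model$F %*% z_src[seq_len(model$m), , drop = FALSE] + model$b
  resp <- dynamic_response(model, z_src, z_dst, delta_t)
  resp - drive
}

# per-gene regression response: (tau/dt)(z_dst - z_src) + z_src (kinetic),
# z_dst - z_src (brownian)
dynamic_response <- function(model, z_src, z_dst, delta_t) {
  if (model$kind == "kinetic") {
    scale <- rep(model$tau / delta_t, each = nrow(z_src))
    (z_dst - z_src) * scale + z_src
  } else {
    z_dst - z_src
  }
}

check_latents_aligned <- function(latents, transitions) {
  if (length(latents$chains) != length(transitions$chains))
    stop("latents and transitions have different chain counts")
  for (ci in seq_along(latents$chains)) {
    zc <- latents$chains[[ci]]
    ch <- transitions$chains[[ci]]
    if (!identical(dim(zc$z_src), dim(ch$y_src)) ||
        !identical(dim(zc$z_dst), dim(ch$y_dst)))
      stop("latent chain ", ci, " is misaligned with its observations")
  }
  invisible(TRUE)
}

#' Simulate a latent trajectory and noisy replicated observations
#'
#' Generative use of the state-space model: the latent path is advanced by
#' [predict_next()] plus i.i.d. Gaussian process noise, and each replicate
#' observes the same latent path plus i.i.d. Gaussian observation noise
#' (homoscedastic across genes).
#'
#' @param model an [dynamics_model()] object.
#' @param z0 initial state vector (length `n`).
#' @param times sampling grid (strictly increasing, >= 2 points).
#' @param sigma_process process-noise standard deviation (scalar, >= 0).
#' @param sigma_obs observation-noise standard deviation: a scalar, or a
#'   vector of length `n` for gene-specific (but time-constant) noise levels.
#' @param replicates number of observation replicates.
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @return list with `latent` (an `n x T` matrix, the noiseless-observation
#'   path) and `series` (an [expression_series()] of the replicates). The
#'   first `m` genes are the regulators.
#' @examples
#' fb <- dynamics_model(matrix(c(0, 0.1, 0.1, 0), 2, 2), kind = "brownian")
#' sim <- simulate_trajectory(fb, c(100, 100), times = 0:5)
#' sim$latent[, 6]  # 161.051: the positive feedback amplifies 10% coupling
#' @export
simulate_trajectory <- function(model, z0, times, sigma_process = 0,
                                sigma_obs = 0, replicates = 1, seed = NULL) {
  stopifnot(inherits(model, "ssm_model"))
  validate_time_grid(times)
  if (any(sigma_process < 0) || any(sigma_obs < 0))
    stop("noise standard deviations must be >= 0")
  if (length(sigma_process) != 1L)
    stop("`sigma_process` must be a scalar")
  if (!length(sigma_obs) %in% c(1L, model$n))
    stop("`sigma_obs` must be a scalar or one value per gene")
  if (length(z0) != model$n) stop("`z0` must have length n")
  if (!is.null(seed)) set.seed(as.integer(seed))

  T_ <- length(times)
  z <- matrix(0, model$n, T_)
  z[, 1L] <- z0
  dts <- diff(times)
  for (k in seq_len(T_ - 1L)) {
    z[, k + 1L] <- predict_next(model, z[, k], dts[k])
    if (sigma_process > 0)
      z[, k + 1L] <- z[, k + 1L] + stats::rnorm(model$n, 0, sigma_process)
  }
  rownames(z) <- rownames(model$F)

  values <- array(0, dim = c(model$n, T_, replicates))
  for (r in seq_len(replicates)) {
    noise <- if (any(sigma_obs > 0))
      matrix(stats::rnorm(model$n * T_, 0, sigma_obs), model$n, T_)
    else 0  # rnorm recycles a length-n sd down the gene dimension
    values[, , r] <- z + noise
  }
  series <- expression_series(
    values, times, gene_ids = rownames(model$F),
    regulators = c(rep(TRUE, model$m), rep(FALSE, model$n - model$m)))
  list(latent = z, series = series)
}

#' Serialize / load a dynamics model
#'
#' Writes three tab-delimited text files under `prefix`: `<prefix>_F.tsv`
#' (influence matrix, rows = genes, columns = regulators), `<prefix>_b.tsv`
#' (gene id, bias), and `<prefix>_meta.tsv` (key-value pairs: kind, tau).
#'
#' @param model an [dynamics_model()] object.
#' @param prefix path prefix for the three output files.
#' @return `prefix`, invisibly (`write_model`); the reloaded model
#'   (`read_model`).
#' @export
write_model <- function(model, prefix) {
  stopifnot(inherits(model, "ssm_model"))
  fm <- data.frame(gene_id = rownames(model$F),
                   apply(model$F, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE)
  colnames(fm) <- c("gene_id", colnames(model$F))
  utils::write.table(fm, paste0(prefix, "_F.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bt <- data.frame(gene_id = rownames(model$F),
                   bias = sprintf("%.17g", model$b))
  utils::write.table(bt, paste0(prefix, "_b.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(key = c("kind", "tau"),
                     value = c(model$kind,
                               if (is.null(model$tau)) "NA"
                               else sprintf("%.17g", model$tau)))
  utils::write.table(meta, paste0(prefix, "_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_model
#' @export
read_model <- function(prefix) {
  fm <- utils::read.table(paste0(prefix, "_F.tsv"), header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  F <- as.matrix(fm[, -1L, drop = FALSE])
  storage.mode(F) <- "double"
  rownames(F) <- fm[[1L]]
  bt <- utils::read.table(paste0(prefix, "_b.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- utils::read.table(paste0(prefix, "_meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  kv <- stats::setNames(meta$value, meta$key)
  tau <- if (identical(kv[["kind"]], "kinetic")) as.numeric(kv[["tau"]]) else NULL
  dynamics_model(F, b = as.numeric(bt$bias), kind = kv[["kind"]], tau = tau)
}
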