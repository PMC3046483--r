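#' Signal-to-noise ratio in decibels
#'
#' Model-fit score used throughout: `10 * log10(sum(observed^2) /
#' sum((observed - predicted)^2))`, a monotone decreasing function of the
#' normalized mean square error. Signal power is the raw sum of squares of
#' the observations (not their variance). A perfect prediction is capped at
#' +300 dB.
#'
#' @param observed,predicted numeric arrays of identical shape, finite.
#' @return decibels (scalar).
#' @examples
#' snr_db(c(3, 4), c(3, 0))  # 10*log10(25/16) = 1.938 dB
#' @export
snr_db <- function(observed, predicted) {
  if (!identical(dim(observed), dim(predicted)) ||
      length(observed) != length(predicted))
    stop("`observed` and `predicted` must have the same shape")
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("inputs must be finite")
  sig <- sum(observed^2)
  if (sig == 0) stop("all-zero observations: the signal-to-noise ratio is undefined")
  err <- sum((observed - predicted)^2)
  if (err == 0) return(300)
  min(300, 10 * log10(sig / err))
}

#' Training signal-to-noise ratio of a fitted model
#'
#' One-step predictions on the training chains: every destination
#' observation is compared against [predict_next()] applied to the inferred
#' source latent of its transition; the pooled [snr_db()] is returned.
#'
#' @param trained an `ssm_trained` object from [train_ssm()].
#' @return decibels (scalar).
#' @export
training_snr <- function(trained) {
  stopifnot(inherits(trained, "ssm_trained"))
  tr <- trained$transitions
  obs <- c()
  pred <- c()
  for (ci in seq_along(tr$chains)) {
    ch <- tr$chains[[ci]]
    zc <- trained$latents$chains[[ci]]
    for (k in seq_along(tr$delta_t)) {
      obs <- c(obs, ch$y_dst[, k])
      pred <- c(pred, predict_next(trained$model, zc$z_src[, k],
                                   tr$delta_t[k]))
    }
  }
  snr_db(obs, pred)
}

#' Genes with replicate-consistent direction of change
#'
#' A gene is "consistent" for a transition when the sign of
#' `y(to) - y(from)` is identical and nonzero in every replicate — the
#' stricter evaluation set for sign prediction. An exact zero change in any
#' replicate excludes the gene.
#'
#' @param series an [expression_series()] object with >= 2 replicates (with
#'   a single replicate, all genes are returned and the result carries a
#'   `single_replicate` attribute, with a warning).
#' @param from_index,to_index grid indices of the transition.
#' @return character vector of consistent gene ids.
#' @export
consistent_genes <- function(series, from_index, to_index) {
  stopifnot(inherits(series, "ssm_series"))
  check_grid_index(series, from_index)
  check_grid_index(series, to_index)
  if (series$n_reps < 2L) {
    warning("single replicate: consistency cannot be assessed, returning all genes")
    return(structure(series$gene_ids, single_replicate = TRUE))
  }
  delta <- series$values[, to_index, , drop = FALSE] -
    series$values[, from_index, , drop = FALSE]
  delta <- matrix(delta, nrow = series$n)
  s <- sign(delta)
  ok <- apply(s, 1L, function(row) all(row != 0) && length(unique(row)) == 1L)
  series$gene_ids[ok]
}

check_grid_index <- function(series, idx) {
  if (!is.numeric(idx) || length(idx) != 1L || idx < 1L || idx > series$n_times)
    stop("time index ", idx, " outside the grid")
  invisible(idx)
}

#' Predict signs of expression change across one transition
#'
#' For every gene, the predicted sign of change from `from_index` to
#' `to_index` is the sign of `predict_next(model, z_from, delta_t) - z_from`,
#' where `z_from` is the inferred latent state at `from_index` averaged
#' across chains ([latent_at_time()]). Accuracy is scored against the
#' replicate-averaged observed change; a zero predicted or observed change
#' counts as incorrect.
#'
#' In the leave-out-last protocol the model is trained on the grid truncated
#' before `to_index`, and this function scores the held-out transition.
#'
#' @param trained an `ssm_trained` object whose grid covers `from_index`.
#' @param series the (full) [expression_series()] providing the observed
#'   truth; `from_index`, `to_index` must be consecutive points of its grid.
#' @param from_index,to_index consecutive grid indices.
#' @return object of class `ssm_eval` (see [eval_report()]) with a per-gene
#'   `signs` table (`gene_id`, `predicted_sign`, `observed_sign`, `correct`).
#' @export
predict_change_signs <- function(trained, series, from_index, to_index) {
  stopifnot(inherits(trained, "ssm_trained"), inherits(series, "ssm_series"))
  check_grid_index(series, from_index)
  check_grid_index(series, to_index)
  if (to_index != from_index + 1L)
    stop("`from_index` and `to_index` must be consecutive grid points")
  if (!identical(trained$transitions$gene_ids, series$gene_ids))
    stop("trained model and series carry different genes")
  if (from_index > length(trained$latents$times))
    stop("`from_index` is outside the trained model's grid")

  delta_t <- series$times[to_index] - series$times[from_index]
  z_from <- latent_at_time(trained, from_index)
  pred_change <- predict_next(trained$model, z_from, delta_t) - z_from
  obs_change <- rowMeans(matrix(series$values[, to_index, , drop = FALSE] -
                                  series$values[, from_index, , drop = FALSE],
                                nrow = series$n))
  predicted_sign <- ifelse(pred_change > 0, "+", "-")
  observed_sign <- ifelse(obs_change > 0, "+", "-")
  correct <- (sign(pred_change) == sign(obs_change)) &
    pred_change != 0 & obs_change != 0
  signs <- data.frame(gene_id = series$gene_ids,
                      predicted_sign = predicted_sign,
                      observed_sign = observed_sign,
                      correct = correct, stringsAsFactors = FALSE)
  cg <- if (series$n_reps >= 2L)
    consistent_genes(series, from_index, to_index)
  else series$gene_ids
  eval_report(signs, consistent_gene_ids = cg)
}

#' Assemble a sign-prediction evaluation report
#'
#' @param signs per-gene data frame with columns `gene_id` and logical
#'   `correct`.
#' @param consistent_gene_ids ids of the replicate-consistent genes
#'   ([consistent_genes()]).
#' @param snr_db training signal-to-noise ratio to attach, if available.
#' @return object of class `ssm_eval`: `snr_db`, `pct_correct_all`,
#'   `pct_correct_consistent`, `consistent_gene_ids`, `n_correct`,
#'   `n_scored`, `signs`.
#' @export
eval_report <- function(signs, consistent_gene_ids, snr_db = NA_real_) {
  stopifnot(is.data.frame(signs), all(c("gene_id", "correct") %in% names(signs)))
  consistent_gene_ids <- intersect(consistent_gene_ids, signs$gene_id)
  n_scored <- nrow(signs)
  n_correct <- sum(signs$correct)
  in_cons <- signs$gene_id %in% consistent_gene_ids
  structure(list(
    snr_db = snr_db,
    pct_correct_all = 100 * n_correct / n_scored,
    pct_correct_consistent = if (any(in_cons))
      100 * sum(signs$correct[in_cons]) / sum(in_cons) else NA_real_,
    consistent_gene_ids = consistent_gene_ids,
    n_correct = n_correct, n_scored = n_scored, signs = signs),
    class = "ssm_eval")
}

#' @export
print.ssm_eval <- function(x, ...) {
  cat(sprintf(
    "ssm_eval: %.1f%% correct signs (%d/%d), %.1f%% on %d consistent genes%s\n",
    x$pct_correct_all, x$n_correct, x$n_scored,
    x$pct_correct_consistent, length(x$consistent_gene_ids),
    if (is.na(x$snr_db)) "" else sprintf(", training SNR %.1f dB", x$snr_db)))
  invisible(x)
}

#' Naive trend-forecast baseline
#'
#' Extrapolates the immediately preceding transition: the predicted sign of
#' change from `t_b` to `t_c` is the sign of the replicate-averaged
#' `y(t_b) - y(t_a)`. A flat trend predicts "-" and is flagged in the
#' `ties` attribute.
#'
#' @param series an [expression_series()] object.
#' @param t_a,t_b,t_c grid indices with `t_a < t_b < t_c`.
#' @return character vector of per-gene signs (`"+"` / `"-"`), named by gene
#'   id, with a logical `ties` attribute.
#' @export
naive_trend_signs <- function(series, t_a, t_b, t_c) {
  stopifnot(inherits(series, "ssm_series"))
  for (idx in c(t_a, t_b, t_c)) check_grid_index(series, idx)
  if (!(t_a < t_b && t_b < t_c)) stop("need t_a < t_b < t_c on the grid")
  trend <- rowMeans(matrix(series$values[, t_b, , drop = FALSE] -
                             series$values[, t_a, , drop = FALSE],
                           nrow = series$n))
  out <- ifelse(trend > 0, "+", "-")
  names(out) <- series$gene_ids
  attr(out, "ties") <- trend == 0
  out
}

#' Exact one-sided binomial sign test
#'
#' Upper-tail probability `P(X >= n_correct)` for
#' `X ~ Binomial(n_scored, p0)`: the chance that a coin biased to be correct
#' with probability `p0` does at least as well as the model.
#'
#' @param n_correct number of correctly predicted signs.
#' @param n_scored number of scored genes.
#' @param p0 baseline success probability, in (0, 1) — e.g. 0.52 when the
#'   baseline forecaster is correct 52% of the time.
#' @return one-sided p-value.
#' @examples
#' binomial_sign_test(10, 10, 0.5)  # 2^-10
#' @export
binomial_sign_test <- function(n_correct, n_scored, p0) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("`p0` must be strictly between 0 and 1")
  if (n_correct < 0 || n_correct > n_scored)
    stop("need 0 <= n_correct <= n_scored")
  stats::pbinom(n_correct - 1, n_scored, p0, lower.tail = FALSE)
}

#' Leave-out-last evaluation of one hyper-parameter setting
#'
#' Fits the state-space model on all time points except the last, then
#' scores the training signal-to-noise ratio and the sign prediction for the
#' held-out final transition (all genes and replicate-consistent genes).
#'
#' @param series an [expression_series()] object with >= 3 time points.
#' @param hyper an [hyper_params()] object.
#' @return object of class `ssm_eval` with the trained model attached as
#'   attribute `"trained"`.
#' @export
evaluate_holdout <- function(series, hyper) {
  stopifnot(inherits(series, "ssm_series"))
  T_ <- series$n_times
  if (T_ < 3L) stop("leave-out-last needs at least 3 time points")
  train_series <- truncate_series(series, T_ - 1L)
  trained <- train_ssm(train_series, hyper)
  ev <- predict_change_signs(trained, series, T_ - 1L, T_)
  ev$snr_db <- training_snr(trained)
  attr(ev, "trained") <- trained
  ev
}

truncate_series <- function(series, last_index) {
  expression_series(series$values[, seq_len(last_index), , drop = FALSE],
                    series$times[seq_len(last_index)],
                    gene_ids = series$gene_ids,
                    regulators = series$regulator_flags)
}

#' Default hyper-parameter grid
#'
#' The grid explored for model selection: state-space coefficient
#' `gamma` in {0, 0.1, 1}, kinetic time constant `tau` in {3, 7} minutes, and
#' L1 weight `lambda` in {1e-4, 5e-3, 0.05, 0.1}.
#'
#' @return named list of numeric vectors (`gamma`, `tau`, `lambda`).
#' @export
default_hyper_grid <- function() {
  list(gamma = c(0, 0.1, 1), tau = c(3, 7),
       lambda = c(1e-4, 5e-3, 0.05, 0.1))
}

#' Exhaustive hyper-parameter grid search
#'
#' Trains one model per (gamma, tau, lambda) cell on all time points except
#' the last, ranks cells by training signal-to-noise ratio, and reports each
#' cell's leave-out-last sign accuracy over all genes and over
#' replicate-consistent genes. A failed cell is kept in the table with
#' `failed = TRUE` rather than aborting the sweep.
#'
#' @param series an [expression_series()] object.
#' @param gamma,tau,lambda numeric grids ([default_hyper_grid()] by default).
#'   `tau` is ignored (single NA cell) for brownian dynamics.
#' @param method,kind optimizer and dynamics kind (see [hyper_params()]).
#' @param epochs,seed passed to [hyper_params()]; the same seed is used for
#'   every cell so cells differ only in their hyper-parameters.
#' @return data frame of class `ssm_grid`, ranked by decreasing
#'   `snr_db`, with columns `dynamics`, `method`, `gamma`, `tau`, `lambda`,
#'   `snr_db`, `pct_correct_all`, `pct_correct_consistent`, `failed`.
#' @export
grid_search <- function(series, gamma = default_hyper_grid()$gamma,
                        tau = default_hyper_grid()$tau,
                        lambda = default_hyper_grid()$lambda,
                        method = "lars", kind = "kinetic",
                        epochs = 100, seed = 1) {
  stopifnot(inherits(series, "ssm_series"))
  if (!length(gamma) || !length(lambda) || (kind == "kinetic" && !length(tau)))
    stop("hyper-parameter grids must be non-empty")
  if (kind == "brownian") tau <- NA_real_
  cells <- expand.grid(gamma = gamma, tau = tau, lambda = lambda,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    out <- data.frame(dynamics = kind, method = method, gamma = cell$gamma,
                      tau = cell$tau, lambda = cell$lambda,
                      snr_db = NA_real_, pct_correct_all = NA_real_,
                      pct_correct_consistent = NA_real_, failed = FALSE,
                      stringsAsFactors = FALSE)
    ev <- tryCatch(
      evaluate_holdout(series, hyper_params(
        gamma = cell$gamma, tau = if (kind == "kinetic") cell$tau else NULL,
        lambda = cell$lambda, method = method, kind = kind,
        epochs = epochs, seed = seed)),
      error = function(e) NULL)
    if (is.null(ev)) {
      out$failed <- TRUE
    } else {
      out$snr_db <- ev$snr_db
      out$pct_correct_all <- ev$pct_correct_all
      out$pct_correct_consistent <- ev$pct_correct_consistent
    }
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$snr_db, res$lambda, na.last = TRUE), ]
  rownames(res) <- NULL
  class(res) <- c("ssm_grid", "data.frame")
  res
}
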