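#' Build replicate transition chains for training
#'
#' Each microarray replicate is an independent measurement, so between two
#' consecutive time points every (source replicate, destination replicate)
#' pairing is a valid observed transition: with `R` replicates there are
#' `R^2` such pairings, and the same pairing is applied uniformly across the
#' whole time course to form a chain (with 2 replicates over 7 time points
#' this yields the 4 replicate sequences of 6 transitions each used for
#' training).
#'
#' Chains are ordered source-major: (1,1), (1,2), ..., (2,1), (2,2), ...
#'
#' @param series an [expression_series()] object with at least 2 time points.
#' @return An object of class `ssm_transitions`: a list with `chains` (each a
#'   list with `src_rep`, `dst_rep`, and `n x (T-1)` matrices `y_src`,
#'   `y_dst` holding the source observation at t_k and the destination
#'   observation at t_{k+1} for every transition k), plus the grid (`times`,
#'   `delta_t`) and gene metadata carried over from the series.
#' @examples
#' es <- expression_series(array(1:12, dim = c(2, 3, 2)), c(0, 3, 6),
#'                         gene_ids = c("a", "b"), regulators = "a")
#' length(build_transition_sequences(es)$chains)  # 4
#' @export
build_transition_sequences <- function(series) {
  stopifnot(inherits(series, "ssm_series"))
  if (series$n_times < 2L)
    stop("need at least 2 time points to build transitions")
  T_ <- series$n_times
  R_ <- series$n_reps
  chains <- vector("list", R_ * R_)
  idx <- 0L
  for (a in seq_len(R_)) {
    for (b in seq_len(R_)) {
      idx <- idx + 1L
      chains[[idx]] <- list(
        src_rep = a, dst_rep = b,
        y_src = matrix(series$values[, seq_len(T_ - 1L), a], nrow = series$n),
        y_dst = matrix(series$values[, 1L + seq_len(T_ - 1L), b], nrow = series$n)
      )
    }
  }
  structure(
    list(chains = chains, times = series$times, delta_t = diff(series$times),
         gene_ids = series$gene_ids, regulator_flags = series$regulator_flags,
         n = series$n, m = series$m, n_times = T_, n_reps = R_),
    class = "ssm_transitions"
  )
}

#' @export
print.ssm_transitions <- function(x, ...) {
  cat(sprintf("ssm_transitions: %d chain(s) of %d transition(s) (%d genes)\n",
              length(x$chains), x$n_times - 1L, x$n))
  invisible(x)
}
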