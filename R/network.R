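#' Bootstrap ensemble of trained state-space models
#'
#' The alternating learner starts from seeded random initializations, so
#' consecutive runs converge to slightly different influence matrices. This
#' repeats [train_ssm()] `runs` times with seeds `base_seed .. base_seed +
#' runs - 1` and stores each run's best-epoch matrix `F*(k)` together with
#' their element-wise mean `F*`, the object edge significance is judged on.
#' A run that fails is retried once with a shifted seed before aborting.
#'
#' @param series an [expression_series()] object.
#' @param hyper an [hyper_params()] object (its own seed is ignored in favor
#'   of the per-run seeds).
#' @param runs number of bootstrap runs (the selection protocol uses 20).
#' @param base_seed first run seed; defaults to `hyper$seed`.
#' @return object of class `ssm_ensemble`: `runs` (list of `F` matrices),
#'   `biases` (list of `b` vectors), `average` (mean matrix `F*`), `hyper`,
#'   `seeds`, `gene_ids`, `regulator_ids`.
#' @export
bootstrap_ensemble <- function(series, hyper, runs = 20,
                               base_seed = hyper$seed) {
  stopifnot(inherits(series, "ssm_series"), inherits(hyper, "ssm_hyper"))
  if (runs < 1) stop("`runs` must be >= 1")
  seeds <- as.integer(base_seed + seq_len(runs) - 1L)
  Fs <- vector("list", runs)
  bs <- vector("list", runs)
  used <- integer(runs)
  for (k in seq_len(runs)) {
    hk <- hyper
    hk$seed <- seeds[k]
    fit <- tryCatch(train_ssm(series, hk), error = function(e) e)
    if (inherits(fit, "error")) {
      hk$seed <- seeds[k] + runs  # one retry with a shifted seed
      fit <- tryCatch(train_ssm(series, hk), error = function(e) e)
      if (inherits(fit, "error"))
        stop("bootstrap run ", k, " failed twice: ", conditionMessage(fit))
    }
    Fs[[k]] <- fit$model$F
    bs[[k]] <- fit$model$b
    used[k] <- hk$seed
  }
  avg <- Reduce(`+`, Fs) / runs
  structure(list(runs = Fs, biases = bs, average = avg, hyper = hyper,
                 seeds = used, gene_ids = rownames(avg),
                 regulator_ids = colnames(avg)),
            class = "ssm_ensemble")
}

#' @export
print.ssm_ensemble <- function(x, ...) {
  cat(sprintf("ssm_ensemble: %d run(s), average F is %d x %d\n",
              length(x$runs), nrow(x$average), ncol(x$average)))
  invisible(x)
}

#' Permutation-based empirical edge p-values
#'
#' Null model for edge significance: for each of `L` rounds, the entries of
#' every run's matrix `F*(k)` are permuted uniformly at random over the whole
#' matrix (independently per run), the permuted matrices are averaged into
#' `P*(l)`, and each cell's p-value is the add-one-corrected fraction of
#' rounds where the permuted average is at least as large in absolute value:
#' `p = (1 + #\{l : |P*(l)| >= |F*|\}) / (L + 1)`. The comparison is
#' two-sided on `|F*|` so strong inhibitory influences are significant too.
#'
#' Each run's permutation stream is seeded from `seed` and a hash of the
#' run's own matrix, not from the run's position in the ensemble, so the
#' p-values are exactly invariant to relabeling the runs while remaining
#' reproducible from `seed`.
#'
#' With `exhaustive = TRUE` all `(n*m)!` cell permutations are enumerated
#' (feasible only for tiny matrices; the round's permutation is then shared
#' by the runs) instead of sampling `L` random ones.
#'
#' @param ensemble an [bootstrap_ensemble()] object.
#' @param L number of random permutation rounds (the selection protocol uses
#'   1000).
#' @param seed integer seed for the permutation draws.
#' @param scope `"matrix"` permutes over all cells; `"row"` / `"column"`
#'   permute within each row / column.
#' @param exhaustive enumerate all permutations instead of sampling
#'   (`scope = "matrix"` only, at most 8 cells).
#' @return object of class `ssm_edge_pvalues`: `pvalues` (n x m matrix in
#'   (0, 1]), `L`, `scope`.
#' @export
permutation_edge_pvalues <- function(ensemble, L = 1000, seed = 1,
                                     scope = c("matrix", "row", "column"),
                                     exhaustive = FALSE) {
  stopifnot(inherits(ensemble, "ssm_ensemble"))
  scope <- match.arg(scope)
  target <- abs(ensemble$average)
  nm <- length(target)
  nr <- nrow(target)
  if (exhaustive) {
    if (scope != "matrix")
      stop("exhaustive enumeration is only implemented for scope = \"matrix\"")
    if (nm > 8L)
      stop("exhaustive enumeration is limited to matrices of at most 8 cells")
    perms <- all_permutations(nm)
    L <- nrow(perms)
    count <- matrix(0L, nr, ncol(target))
    for (l in seq_len(L)) {
      P <- Reduce(`+`, lapply(ensemble$runs, function(Fk)
        matrix(Fk[perms[l, ]], nr))) / length(ensemble$runs)
      count <- count + (abs(P) >= target)
    }
  } else {
    if (L < 1) stop("`L` must be >= 1")
    nc <- ncol(target)
    K <- length(ensemble$runs)
    # accumulate the K permuted matrices round by round; each run's stream
    # is keyed by its own content so run order cannot matter
    acc <- array(0, dim = c(nr, nc, L))
    for (Fk in ensemble$runs) {
      set.seed(run_stream_seed(seed, Fk))
      for (l in seq_len(L)) {
        idx <- permutation_indices(nr, nc, scope)
        acc[, , l] <- acc[, , l] + matrix(Fk[idx], nr)
      }
    }
    count <- matrix(0L, nr, nc)
    for (l in seq_len(L))
      count <- count + (abs(acc[, , l] / K) >= target)
  }
  p <- (1 + count) / (L + 1)
  dimnames(p) <- dimnames(ensemble$average)
  structure(list(pvalues = p, L = L, scope = scope),
            class = "ssm_edge_pvalues")
}

# content hash of a run's matrix, mixed with the user seed; keeps each run's
# permutation stream attached to the run itself rather than to its position
run_stream_seed <- function(seed, Fk) {
  v <- as.numeric(Fk)
  h <- sum(abs(v)) + sum(v * seq_along(v) %% 97) + length(v)
  (as.integer(seed) + (floor(h * 1e4) %% 1000000007)) %% 2147483647
}

# linear cell indices of one random permutation under the given scope
permutation_indices <- function(nr, nc, scope) {
  base <- matrix(seq_len(nr * nc), nr)
  switch(scope,
    matrix = sample.int(nr * nc),
    row = {
      out <- base
      for (i in seq_len(nr)) out[i, ] <- base[i, sample.int(nc)]
      as.integer(out)
    },
    column = {
      out <- base
      for (j in seq_len(nc)) out[, j] <- base[sample.int(nr), j]
      as.integer(out)
    })
}

# all permutations of 1..n as rows (n! x n); recursive, for tiny n only
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Threshold the averaged influence matrix into a signed network
#'
#' Emits the edges whose permutation p-value falls below `alpha` (the
#' selection protocol uses 0.001), carrying the bootstrap-averaged weight
#' and its sign (positive = excitatory, negative = inhibitory).
#'
#' @param ensemble an [bootstrap_ensemble()] object.
#' @param sig an [permutation_edge_pvalues()] object of matching shape.
#' @param alpha significance level in (0, 1].
#' @return object of class `ssm_network`: a data frame `edges` with columns
#'   `regulator`, `target`, `weight`, `sign`, `p_value`, plus `alpha` and the
#'   gene/regulator id sets.
#' @export
threshold_network <- function(ensemble, sig, alpha = 0.001) {
  stopifnot(inherits(ensemble, "ssm_ensemble"),
            inherits(sig, "ssm_edge_pvalues"))
  if (!identical(dim(ensemble$average), dim(sig$pvalues)))
    stop("ensemble and p-value shapes disagree")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("`alpha` must be in (0, 1]")
  keep <- which(sig$pvalues < alpha, arr.ind = TRUE)
  edges <- data.frame(
    regulator = ensemble$regulator_ids[keep[, 2L]],
    target = ensemble$gene_ids[keep[, 1L]],
    weight = ensemble$average[keep],
    p_value = sig$pvalues[keep],
    stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$weight >= 0, "+", "-")
  edges <- edges[order(edges$p_value, -abs(edges$weight)),
                 c("regulator", "target", "weight", "sign", "p_value")]
  rownames(edges) <- NULL
  structure(list(edges = edges, alpha = alpha,
                 gene_ids = ensemble$gene_ids,
                 regulator_ids = ensemble$regulator_ids),
            class = "ssm_network")
}

#' @export
print.ssm_network <- function(x, ...) {
  cat(sprintf("ssm_network: %d edge(s) at p < %g (%d genes, %d regulators)\n",
              nrow(x$edges), x$alpha, length(x$gene_ids),
              length(x$regulator_ids)))
  invisible(x)
}

#' Degree and hub summary of a thresholded network
#'
#' Ranks genes by their influence in the network: out-degree (targets
#' regulated), in-degree (incoming regulations), and the summed absolute
#' incoming weight. Hubs combine a high out-degree with strong incoming
#' regulation.
#'
#' @param network an [threshold_network()] object.
#' @return data frame with columns `gene_id`, `out_degree`, `in_degree`,
#'   `in_strength`, ranked by decreasing out-degree then in-strength.
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "ssm_network"))
  ids <- network$gene_ids
  out_deg <- vapply(ids, function(g) sum(network$edges$regulator == g),
                    integer(1))
  in_deg <- vapply(ids, function(g) sum(network$edges$target == g),
                   integer(1))
  in_str <- vapply(ids, function(g)
    sum(abs(network$edges$weight[network$edges$target == g])), numeric(1))
  res <- data.frame(gene_id = ids, out_degree = out_deg, in_degree = in_deg,
                    in_strength = in_str, stringsAsFactors = FALSE)
  res <- res[order(-res$out_degree, -res$in_strength), ]
  rownames(res) <- NULL
  res
}

#' Export a network as an edge list or SIF file
#'
#' `write_edge_list` writes the tab-delimited table
#' (regulator, target, weight, sign, p_value); `write_sif` writes the
#' Cytoscape SIF form `regulator<TAB>activates|represses<TAB>target`.
#'
#' @param network an [threshold_network()] object.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ssm_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "ssm_network"))
  rel <- ifelse(network$edges$sign == "+", "activates", "represses")
  writeLines(paste(network$edges$regulator, rel, network$edges$target,
                   sep = "\t"), path)
  invisible(path)
}
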