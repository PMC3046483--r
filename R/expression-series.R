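#' Replicated gene-expression time series
#'
#' Container for an expression time course of `n` genes observed at `T`
#' ordered time points with `R` replicates per time point. Genes flagged as
#' regulators (transcription factors) are reordered to occupy the first `m`
#' rows, so that an influence matrix fitted to the series is literally
#' `n x m` with regulator columns 1..m; the permutation applied to the input
#' order is recorded in the `"permutation"` attribute.
#'
#' Values are used on the scale they are supplied on (e.g. MAS5 signal); no
#' transform is applied. Missing or non-finite cells are rejected: the model
#' assumes a complete table.
#'
#' @param values numeric array `n x T x R` (a matrix is treated as one
#'   replicate), expression on the analysis scale.
#' @param times numeric vector of `T` strictly increasing sampling times, in
#'   minutes.
#' @param gene_ids character vector of `n` unique gene identifiers. Defaults
#'   to the rownames of `values` or `g1..gn`.
#' @param regulators character vector of gene identifiers to flag as
#'   regulators, or a logical vector of length `n`. At least one required.
#'
#' @return An object of class `ssm_series`: a list with elements `gene_ids`,
#'   `regulator_flags`, `times`, `values` (reordered array), and counts
#'   `n`, `m`, `n_times`, `n_reps`.
#' @examples
#' y <- array(rexp(4 * 3 * 2, 1 / 100), dim = c(4, 3, 2))
#' es <- expression_series(y, times = c(0, 3, 6),
#'                         gene_ids = c("a", "b", "c", "d"),
#'                         regulators = c("c", "a"))
#' es$gene_ids  # regulators first
#' @export
expression_series <- function(values, times, gene_ids = NULL,
                              regulators = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an n x T x R array (or an n x T matrix)")
  n <- dim(values)[1L]
  validate_time_grid(times)
  if (length(times) != dim(values)[2L])
    stop("length(times) does not match the time dimension of `values`")
  if (!all(is.finite(values)))
    stop("expression values contain missing or non-finite cells")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != n) stop("need one gene id per row of `values`")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")

  if (is.null(regulators)) stop("at least one regulator must be flagged")
  if (is.logical(regulators)) {
    if (length(regulators) != n)
      stop("logical `regulators` must have length n")
    flags <- regulators
  } else {
    regulators <- as.character(regulators)
    unknown <- setdiff(regulators, gene_ids)
    if (length(unknown))
      stop("regulator ids not in the series: ",
           paste(unknown, collapse = ", "))
    flags <- gene_ids %in% regulators
  }
  m <- sum(flags)
  if (m < 1L) stop("at least one regulator must be flagged")

  # canonical ordering: regulators first, original relative order preserved
  perm <- order(!flags)
  values <- values[perm, , , drop = FALSE]
  gene_ids <- gene_ids[perm]
  flags <- flags[perm]
  dimnames(values) <- list(gene_ids, format_times(times),
                           paste0("r", seq_len(dim(values)[3L])))

  structure(
    list(gene_ids = gene_ids, regulator_flags = flags, times = as.numeric(times),
         values = values, n = n, m = m, n_times = length(times),
         n_reps = dim(values)[3L]),
    permutation = perm,
    class = "ssm_series"
  )
}

validate_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L)
    stop("the time grid needs at least 2 numeric points")
  if (!all(is.finite(times))) stop("time grid contains non-finite values")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  invisible(times)
}

format_times <- function(times) {
  vapply(times, function(t) format(t, scientific = FALSE, trim = TRUE),
         character(1))
}

#' @export
print.ssm_series <- function(x, ...) {
  cat(sprintf(
    "ssm_series: %d genes (%d regulators), %d time points (%s min), %d replicate(s)\n",
    x$n, x$m, x$n_times, paste(format_times(x$times), collapse = ", "),
    x$n_reps))
  invisible(x)
}

#' Read an expression time-series table
#'
#' Parses the tab-delimited exchange format: a header row
#' `gene_id<TAB><time>_r<rep>...` (e.g. `0_r1  0_r2  3_r1 ...`) followed by
#' one row per gene, '.' decimal separator, UTF-8. Every time point must
#' carry the same set of replicates.
#'
#' @param path path to the expression table.
#' @param regulators path to a plain-text regulator list (one id per line),
#'   or a character vector of ids.
#' @param log2_transform apply `log2(x + 1)` after loading (off by default;
#'   the table is otherwise used on its native scale).
#' @return An [expression_series()] object.
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path, regulators, log2_transform = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("expression table has no measurement columns")
  ids <- as.character(tab[[1L]])
  meas <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(meas) <- "double"

  keys <- regmatches(colnames(meas),
                     regexec("^(.+)_r([0-9]+)$", colnames(meas)))
  bad <- vapply(keys, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed column header(s): ",
         paste(colnames(meas)[bad], collapse = ", "))
  col_time <- as.numeric(vapply(keys, `[`, character(1), 2L))
  col_rep <- as.integer(vapply(keys, `[`, character(1), 3L))
  times <- sort(unique(col_time))
  reps <- sort(unique(col_rep))
  values <- array(NA_real_, dim = c(length(ids), length(times), length(reps)))
  for (j in seq_along(col_time)) {
    k <- match(col_time[j], times)
    r <- match(col_rep[j], reps)
    if (!is.na(values[1L, k, r]))
      stop("duplicate column for time ", col_time[j], " replicate ", col_rep[j])
    values[, k, r] <- meas[, j]
  }
  if (anyNA(values))
    stop("replicate structure is ragged: every time point needs the same replicates")
  if (log2_transform) values <- log2(values + 1)

  if (is.character(regulators) && length(regulators) == 1L &&
      file.exists(regulators)) {
    regulators <- read_gene_list(regulators)
  }
  expression_series(values, times, gene_ids = ids, regulators = regulators)
}

#' Write an expression time-series table
#'
#' Inverse of [read_expression_table()]: values are serialized with 17
#' significant digits so a write/read round trip reproduces the series
#' bit-exactly.
#'
#' @param series an [expression_series()] object.
#' @param path output path.
#' @export
write_expression_table <- function(series, path) {
  stopifnot(inherits(series, "ssm_series"))
  cols <- list(gene_id = series$gene_ids)
  for (k in seq_len(series$n_times)) {
    for (r in seq_len(series$n_reps)) {
      nm <- paste0(format_times(series$times[k]), "_r", r)
      cols[[nm]] <- sprintf("%.17g", series$values[, k, r])
    }
  }
  tab <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path file with one gene id per line; blank lines are dropped.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path, encoding = "UTF-8")
  ids <- trimws(ids)
  ids[nzchar(ids)]
}
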