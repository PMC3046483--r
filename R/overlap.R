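#' Gene list
#'
#' A named set of unique gene identifiers, the unit of the overlap
#' randomization test.
#'
#' @param ids character vector of identifiers (deduplicated, order kept).
#' @param name label for reports.
#' @return object of class `ssm_gene_list`.
#' @export
gene_list <- function(ids, name = "list") {
  ids <- unique(as.character(ids))
  structure(list(name = name, ids = ids), class = "ssm_gene_list")
}

#' @export
print.ssm_gene_list <- function(x, ...) {
  cat(sprintf("gene list '%s': %d id(s)\n", x$name, length(x$ids)))
  invisible(x)
}

as_gene_list <- function(x, name = "list") {
  if (inherits(x, "ssm_gene_list")) x else gene_list(x, name)
}

#' Randomization test for gene-list overlap
#'
#' Monte-Carlo test of whether two gene lists share more identifiers than
#' expected by chance: `R` times, two random lists of the observed sizes are
#' drawn uniformly without replacement from the universe (both lists redrawn
#' each round) and the p-value is the fraction of rounds whose intersection
#' is at least as large as the observed one, `p = n / R`. A p-value of 0
#' (no round reached the observed overlap) is reported with
#' `flag_floor = TRUE` and should be read as `p < 1/R`.
#'
#' @param a,b gene lists ([gene_list()] objects or character vectors).
#' @param universe the identifier universe both lists are drawn from (e.g.
#'   all assayed genes); must contain `a` and `b`.
#' @param R number of random list pairs (10000 for single tests; matrices
#'   use 1000 for speed).
#' @param seed integer seed.
#' @return object of class `ssm_overlap`: `intersection_size`, `p_value`,
#'   `replicates_used`, `flag_floor`.
#' @export
randomization_overlap_test <- function(a, b, universe, R = 10000, seed = 1) {
  a <- as_gene_list(a, "a")
  b <- as_gene_list(b, "b")
  universe <- as_gene_list(universe, "universe")
  if (R < 1) stop("`R` must be >= 1")
  off_a <- setdiff(a$ids, universe$ids)
  off_b <- setdiff(b$ids, universe$ids)
  if (length(off_a) || length(off_b))
    stop("ids outside the universe: ",
         paste(unique(c(off_a, off_b)), collapse = ", "))
  observed <- length(intersect(a$ids, b$ids))
  U <- length(universe$ids)
  na <- length(a$ids)
  nb <- length(b$ids)
  set.seed(as.integer(seed))
  hits <- 0L
  member <- logical(U)
  for (r in seq_len(R)) {
    ia <- sample.int(U, na)
    ib <- sample.int(U, nb)
    member[ia] <- TRUE
    inter <- sum(member[ib])
    member[ia] <- FALSE
    if (inter >= observed) hits <- hits + 1L
  }
  structure(list(intersection_size = observed, p_value = hits / R,
                 replicates_used = R, flag_floor = hits == 0L),
            class = "ssm_overlap")
}

#' @export
print.ssm_overlap <- function(x, ...) {
  cat(sprintf("overlap %d, p %s (R = %d)\n", x$intersection_size,
              if (x$flag_floor) sprintf("< %g", 1 / x$replicates_used)
              else format(x$p_value), x$replicates_used))
  invisible(x)
}

#' Pairwise overlap matrix of gene lists
#'
#' Assembles the square summary used to delineate co-regulated modules from a
#' collection of gene lists: the diagonal holds each list's size, cells above
#' the diagonal the pairwise intersection sizes, and cells below the diagonal
#' the randomization-test p-values ([randomization_overlap_test()]). A
#' p-value of 0 means p < 1/R; such cells are marked in the `"floor"`
#' attribute (a logical matrix).
#'
#' @param lists a list of two or more gene lists (named, or carrying
#'   [gene_list()] names).
#' @param universe the shared identifier universe.
#' @param R randomization rounds per pair (default 1000 to keep matrices
#'   fast).
#' @param seed integer seed; each pair derives its own sub-seed so the
#'   matrix is reproducible independent of evaluation order.
#' @return numeric matrix of class `ssm_overlap_matrix` with list names as
#'   dimnames and attributes `R` and `floor`.
#' @export
overlap_matrix <- function(lists, universe, R = 1000, seed = 1) {
  if (length(lists) < 2L) stop("need at least 2 gene lists")
  nms <- names(lists)
  lists <- lapply(seq_along(lists), function(i) {
    l <- as_gene_list(lists[[i]], paste0("list", i))
    if (!is.null(nms) && nzchar(nms[i])) l$name <- nms[i]
    l
  })
  nms <- vapply(lists, function(l) l$name, character(1))
  k <- length(lists)
  M <- matrix(0, k, k, dimnames = list(nms, nms))
  floor_flag <- matrix(FALSE, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) M[i, i] <- length(lists[[i]]$ids)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      M[i, j] <- length(intersect(lists[[i]]$ids, lists[[j]]$ids))
      res <- randomization_overlap_test(
        lists[[i]], lists[[j]], universe, R = R,
        seed = as.integer(seed + (i - 1L) * k + j))
      M[j, i] <- res$p_value
      floor_flag[j, i] <- res$flag_floor
    }
  }
  structure(M, R = R, floor = floor_flag,
            class = c("ssm_overlap_matrix", "matrix", "array"))
}

#' @export
print.ssm_overlap_matrix <- function(x, ...) {
  cat(sprintf(
    "overlap matrix (R = %d): diagonal = list size, above = intersection, below = p-value (0 means < %g)\n",
    attr(x, "R"), 1 / attr(x, "R")))
  print(unclass_keep_dimnames(x))
  invisible(x)
}

unclass_keep_dimnames <- function(x) {
  attr(x, "R") <- NULL
  attr(x, "floor") <- NULL
  unclass(x)
}

#' Write an overlap matrix report
#'
#' Tab-delimited with a `#`-prefixed legend header; p-value cells that hit
#' the Monte-Carlo floor are rendered as `<1/R`.
#'
#' @param mat an [overlap_matrix()] result.
#' @param path output path.
#' @export
write_overlap_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "ssm_overlap_matrix"))
  R <- attr(mat, "R")
  fl <- attr(mat, "floor")
  cells <- matrix(format(unclass_keep_dimnames(mat), trim = TRUE),
                  nrow(mat), dimnames = dimnames(mat))
  cells[fl] <- sprintf("<%g", 1 / R)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# overlap matrix, randomization test with R = %d", R),
    "# diagonal: list size; above diagonal: intersection size; below diagonal: p-value"),
    con)
  utils::write.table(cbind(list = rownames(cells), cells), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
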