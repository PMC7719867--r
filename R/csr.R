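#' Convert a dense matrix to coordinate (COO) form
#'
#' First stage of the sparse compression: scan the dense matrix in row-major
#' order and keep only the nonzero cells as parallel row-index, column-index
#' and value vectors, abolishing every zero. Indices are 0-based, the native
#' convention of the compressed sparse row format.
#'
#' @param m Dense numeric matrix of nonnegative integers.
#' @return A list with integer vectors `row`, `col`, `value` (triples sorted
#'   by row then column, no duplicates) and scalars `n_rows`, `n_cols`.
#' @seealso [compress_rows()]
#' @export
dense_to_coo <- function(m) {
  stopifnot(is.matrix(m))
  if (any(m < 0) || any(m != round(m))) {
    stop("matrix must contain nonnegative integers", call. = FALSE)
  }
  nz <- which(m != 0, arr.ind = TRUE)
  ord <- order(nz[, 1L], nz[, 2L])  # row-major
  nz <- nz[ord, , drop = FALSE]
  list(row = as.integer(nz[, 1L] - 1L),
       col = as.integer(nz[, 2L] - 1L),
       value = as.integer(m[nz]),
       n_rows = nrow(m), n_cols = ncol(m))
}

#' Compress a sorted row-coordinate vector into index pointers
#'
#' Second stage of the compression: the sorted row vector of the coordinate
#' form is replaced by adjacent pairs of index pointers, one pair per row.
#' `p[i+1] - p[i]` is the number of stored entries in row `i` (0-based), so
#' the entries of row `i` occupy positions `p[i]..p[i+1]-1` of the column
#' and value vectors.
#'
#' @param r Integer vector of 0-based row indices, sorted ascending.
#' @param n_rows Number of matrix rows; every element of `r` must be
#'   `< n_rows`.
#' @return Numeric index-pointer vector of length `n_rows + 1`, starting
#'   at 0 and ending at `length(r)`.
#' @examples
#' compress_rows(c(0, 0, 1, 3), 4)  # 0 2 3 3 4
#' @export
compress_rows <- function(r, n_rows) {
  r <- as.integer(r)
  if (is.unsorted(r)) {
    stop("row vector must be sorted ascending", call. = FALSE)
  }
  if (length(r) > 0L && (min(r) < 0L || max(r) >= n_rows)) {
    stop("row index out of range [0, ", n_rows, ")", call. = FALSE)
  }
  counts <- tabulate(r + 1L, nbins = n_rows)
  as.numeric(c(0, cumsum(counts)))
}

#' Construct a labeled compressed sparse row matrix
#'
#' The central container of the package: a CSR matrix whose rows are genomes
#' and whose columns are features (Pfam domains or domain-architecture
#' strings). Stored values are occurrence counts, or all 1 for a binary
#' presence/absence matrix.
#'
#' @param p Index-pointer vector, length `n_rows + 1`, `p[1] == 0`,
#'   nondecreasing.
#' @param j 0-based column indices; strictly increasing within each row.
#' @param x Stored values, all nonzero.
#' @param row_labels Character vector of unique genome ids, row order.
#' @param col_labels Character vector of unique feature ids, column order.
#' @param is_binary Logical flag; if `TRUE` every stored value must be 1.
#' @return An object of class `labeled_csr`.
#' @export
labeled_csr <- function(p, j, x, row_labels, col_labels, is_binary = FALSE) {
  m <- structure(list(p = as.numeric(p), j = as.integer(j), x = as.numeric(x),
                      row_labels = as.character(row_labels),
                      col_labels = as.character(col_labels),
                      is_binary = isTRUE(is_binary)),
                 class = "labeled_csr")
  validate_labeled_csr(m)
  m
}

validate_labeled_csr <- function(m) {
  n_rows <- length(m$row_labels)
  nnz <- length(m$j)
  if (length(m$p) != n_rows + 1L) stop("index pointer has wrong length")
  if (m$p[1L] != 0) stop("index pointer must start at 0")
  if (any(diff(m$p) < 0)) stop("index pointer must be nondecreasing")
  if (m$p[n_rows + 1L] != nnz || length(m$x) != nnz) {
    stop("index pointer end does not match number of stored entries")
  }
  if (nnz > 0L && (min(m$j) < 0L || max(m$j) >= length(m$col_labels))) {
    stop("column index out of range")
  }
  if (nnz > 1L) {
    row_of <- rep.int(seq_len(n_rows), times = diff(m$p))
    same_row <- diff(row_of) == 0L
    if (any(same_row & diff(m$j) <= 0L)) {
      stop("column indices must be strictly increasing within each row")
    }
  }
  if (any(m$x == 0)) stop("stored values must be nonzero")
  if (m$is_binary && nnz > 0L && any(m$x != 1)) {
    stop("binary matrix must store only 1s")
  }
  if (anyDuplicated(m$row_labels)) stop("row labels must be unique")
  if (anyDuplicated(m$col_labels)) stop("column labels must be unique")
  invisible(m)
}

# positions (1-based, into j/x) of stored entries of 1-based row i
row_slice <- function(m, i) {
  lo <- m$p[i]
  hi <- m$p[i + 1L]
  if (hi <= lo) integer(0) else (lo + 1L):hi
}

# positions of stored entries of several 1-based rows, concatenated
rows_slice <- function(m, rows) {
  len <- as.integer(m$p[rows + 1L] - m$p[rows])
  if (sum(len) == 0L) return(integer(0))
  sequence(len, from = as.integer(m$p[rows]) + 1L)
}

#' @export
dim.labeled_csr <- function(x) {
  c(length(x$row_labels), length(x$col_labels))
}

#' @export
print.labeled_csr <- function(x, ...) {
  cat(sprintf("labeled_csr: %d genomes x %d features, %d stored values (%s)\n",
              length(x$row_labels), length(x$col_labels), length(x$j),
              if (x$is_binary) "binary" else "counts"))
  invisible(x)
}

#' @export
as.matrix.labeled_csr <- function(x, ...) {
  n_rows <- length(x$row_labels)
  n_cols <- length(x$col_labels)
  d <- matrix(0, n_rows, n_cols,
              dimnames = list(x$row_labels, x$col_labels))
  for (i in seq_len(n_rows)) {
    s <- row_slice(x, i)
    d[i, x$j[s] + 1L] <- x$x[s]
  }
  d
}

#' Build a labeled CSR matrix from a dense labeled matrix
#'
#' Composition of [dense_to_coo()] and [compress_rows()]; mainly used for
#' testing and for small matrices. The matrix builders stream genome by
#' genome instead and never materialize a dense intermediate.
#'
#' @param m Dense nonnegative integer matrix with `dimnames` giving genome
#'   and feature labels (generated labels are supplied when absent).
#' @param is_binary Mark (and require) the matrix as binary.
#' @return A `labeled_csr`.
#' @export
csr_from_dense <- function(m, is_binary = FALSE) {
  coo <- dense_to_coo(m)
  p <- compress_rows(coo$row, coo$n_rows)
  rl <- rownames(m)
  cl <- colnames(m)
  if (is.null(rl)) rl <- sprintf("row%d", seq_len(nrow(m)))
  if (is.null(cl)) cl <- sprintf("col%d", seq_len(ncol(m)))
  labeled_csr(p, coo$col, coo$value, rl, cl, is_binary = is_binary)
}

#' Reduce a count matrix to presence/absence
#'
#' Keeps the sparsity pattern and labels, replaces every stored value by 1
#' and sets the binary flag. Idempotent.
#'
#' @param m A `labeled_csr`.
#' @return A binary `labeled_csr` with the same pattern and labels.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "labeled_csr"))
  m$x <- rep(1, length(m$x))
  m$is_binary <- TRUE
  m
}
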