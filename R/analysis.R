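#' Row and column labels of a matrix
#'
#' @param m A `labeled_csr`.
#' @return Character vector of genome ids (`get_rows`) or feature ids
#'   (`get_columns`), in matrix order.
#' @export
get_rows <- function(m) {
  stopifnot(inherits(m, "labeled_csr"))
  m$row_labels
}

#' @rdname get_rows
#' @export
get_columns <- function(m) {
  stopifnot(inherits(m, "labeled_csr"))
  m$col_labels
}

# map requested labels to 1-based indices, erroring on unknowns
resolve_labels <- function(requested, available, what) {
  idx <- match(requested, available)
  if (anyNA(idx)) {
    stop("unknown ", what, " label: ", requested[which(is.na(idx))[1L]],
         call. = FALSE)
  }
  if (anyDuplicated(requested)) {
    stop("duplicate ", what, " label in query: ",
         requested[duplicated(requested)][1L], call. = FALSE)
  }
  idx
}

#' Row-wise summation over a genome/feature subset
#'
#' For each requested genome, sums the stored values (counts, or 0/1 for a
#' binary matrix) over the requested features.
#'
#' @param m A `labeled_csr`.
#' @param list_row Character vector of genome ids (default: all rows).
#' @param list_col Character vector of feature ids (default: all columns).
#' @return Data frame with columns `row_name`, `row_sum`, one row per
#'   requested genome, in `list_row` order.
#' @export
sum_rows <- function(m, list_row = get_rows(m), list_col = get_columns(m)) {
  stopifnot(inherits(m, "labeled_csr"))
  rows <- resolve_labels(list_row, m$row_labels, "genome")
  cols <- resolve_labels(list_col, m$col_labels, "feature")
  col_mask <- logical(length(m$col_labels))
  col_mask[cols] <- TRUE
  sums <- vapply(rows, function(i) {
    s <- row_slice(m, i)
    sum(m$x[s][col_mask[m$j[s] + 1L]])
  }, numeric(1))
  data.frame(row_name = list_row, row_sum = sums,
             stringsAsFactors = FALSE, row.names = NULL)
}

# total stored value per requested column over requested rows (numeric
# vector aligned with cols); shared by sum_columns and cal_core.
# whole-matrix queries read j/x directly; binary matrices count presences
# with a single tabulate pass.
col_totals <- function(m, rows, cols) {
  n_cols <- length(m$col_labels)
  if (length(rows) == length(m$row_labels) &&
      identical(as.integer(rows), seq_along(m$row_labels))) {
    jj <- m$j
    xx <- m$x
  } else {
    take <- rows_slice(m, rows)
    jj <- m$j[take]
    xx <- m$x[take]
  }
  totals <- numeric(n_cols)
  if (length(jj) > 0L) {
    if (m$is_binary) {
      totals <- as.numeric(tabulate(jj + 1L, nbins = n_cols))
    } else {
      agg <- rowsum(xx, jj, reorder = FALSE)
      totals[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    }
  }
  totals[cols]
}

#' Column-wise summation over a genome/feature subset
#'
#' For each requested feature, sums the stored values over the requested
#' genomes. On a binary matrix this is the number of genomes carrying the
#' feature; on a count matrix it is the total occurrence count — e.g. the
#' per-genome copy number of a toxin architecture when `list_row` is a
#' single genome.
#'
#' @inheritParams sum_rows
#' @return Data frame with columns `col_name`, `col_sum`, one row per
#'   requested feature, in `list_col` order.
#' @export
sum_columns <- function(m, list_row = get_rows(m), list_col = get_columns(m)) {
  stopifnot(inherits(m, "labeled_csr"))
  rows <- resolve_labels(list_row, m$row_labels, "genome")
  cols <- resolve_labels(list_col, m$col_labels, "feature")
  data.frame(col_name = list_col, col_sum = col_totals(m, rows, cols),
             stringsAsFactors = FALSE, row.names = NULL)
}

# exact inclusive test of count/n >= cutoff for cutoffs expressible with at
# most 6 decimal places: all products stay far below 2^53, so comparisons
# are integer-exact. 0.95 * 20 == 19.000000000000004 in floating point,
# which would wrongly reject a feature present in exactly 19 of 20 genomes.
fraction_geq <- function(count, n, cutoff) {
  num <- round(cutoff * 1e6)
  g <- gcd(num, 1e6)
  num <- num / g
  den <- 1e6 / g
  count * den >= num * n
}

gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  if (a == 0) 1 else a
}

#' Core features at a conservation cutoff
#'
#' A feature (functional domain or domain architecture) is core for a genome
#' set when it is present in at least `cutoff` of the queried genomes — at
#' the default 95%, "95% or more", boundary inclusive. The fraction
#' denominator is the number of queried genomes, not the total matrix rows.
#'
#' Requires a binary matrix (use [load_binary_matrix()] or [binarize()]):
#' on a count matrix a cell of 5 would contribute 5 to the presence count,
#' so the function refuses rather than silently thresholding.
#'
#' The cutoff comparison is performed as an exact rational test (for cutoffs
#' expressible with up to 6 decimal places), so a feature present in exactly
#' 19 of 20 genomes is retained at cutoff 0.95 despite `0.95 * 20` exceeding
#' 19 in floating point.
#'
#' @inheritParams sum_rows
#' @param cutoff Conservation cutoff in `[0, 1]`; default 0.95.
#' @return Data frame with columns `col_name`, `genome_count`, `fraction`,
#'   one row per requested feature meeting the cutoff, in `list_col` order.
#' @export
cal_core <- function(m, list_row = get_rows(m), list_col = get_columns(m),
                     cutoff = 0.95) {
  stopifnot(inherits(m, "labeled_csr"))
  if (!m$is_binary) {
    stop("cal_core requires a binary presence/absence matrix; ",
         "load it with load_binary_matrix() or apply binarize() first",
         call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff > 1) {
    stop("cutoff must be a single number in [0, 1]", call. = FALSE)
  }
  if (length(list_row) == 0L) {
    stop("list_row is empty: the conservation fraction is undefined",
         call. = FALSE)
  }
  rows <- resolve_labels(list_row, m$row_labels, "genome")
  cols <- resolve_labels(list_col, m$col_labels, "feature")
  counts <- col_totals(m, rows, cols)
  n <- length(rows)
  keep <- fraction_geq(counts, n, cutoff)
  data.frame(col_name = list_col[keep],
             genome_count = counts[keep],
             fraction = counts[keep] / n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Protein ids behind genome/feature associations
#'
#' Looks up, in the protein-id store written by a build with `keep = TRUE`,
#' every protein of a requested genome annotated with a requested feature
#' (a Pfam domain in domain mode; a full architecture string in architecture
#' mode). Every emitted pair corresponds to a nonzero matrix cell.
#'
#' @inheritParams sum_rows
#' @param output Optional path; when given, the report is also written there
#'   as a headerless 3-column TSV (GenomeId, Feature, ProteinId).
#' @return Data frame with columns `genome_id`, `feature`, `protein_id`,
#'   sorted bytewise by (genome, feature, protein).
#' @export
get_protein_ids <- function(m, list_row = get_rows(m),
                            list_col = get_columns(m), output = NULL) {
  stopifnot(inherits(m, "labeled_csr"))
  store <- attr(m, "protein_index")
  if (is.null(store)) {
    stop("no protein-id store: rebuild the matrix folder with the keep ",
         "option to record protein ids", call. = FALSE)
  }
  resolve_labels(list_row, m$row_labels, "genome")
  resolve_labels(list_col, m$col_labels, "feature")
  sel <- store$genome_id %in% list_row & store$feature %in% list_col
  out <- store[sel, c("genome_id", "feature", "protein_id"), drop = FALSE]
  ord <- order(out$genome_id, out$feature, out$protein_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(output)) {
    con <- file(output, "wb")
    on.exit(close(con))
    if (nrow(out) > 0L) {
      writeLines(paste(out$genome_id, out$feature, out$protein_id,
                       sep = "\t"), con, useBytes = TRUE)
    }
  }
  out
}
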