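FORMAT_VERSION <- "1"

matrix_files <- c(meta = "metadata.dcf", p = "indptr.txt", j = "indices.txt",
                  x = "values.txt", rows = "rows.txt", cols = "cols.txt")
PROTEIN_STORE <- "proteins.tsv"

#' Save a labeled CSR matrix to a matrix folder
#'
#' Writes a versioned folder: a metadata file (format version, shape, number
#' of stored values, binary flag), three newline-delimited array files
#' (index pointers, column indices, values), two label index files (row and
#' column labels, one per line, UTF-8), and — when the matrix carries a
#' protein-id store — a sorted 3-column TSV of (genome, feature, protein)
#' associations. All files are plain text with no timestamps, so a fixed
#' manifest and inputs always produce byte-identical folders.
#'
#' @param m A `labeled_csr`.
#' @param folder Destination directory (created if needed).
#' @param overwrite If `FALSE` (default) refuse to write into a folder that
#'   already contains a matrix.
#' @return `folder`, invisibly.
#' @export
save_matrix <- function(m, folder, overwrite = FALSE) {
  stopifnot(inherits(m, "labeled_csr"))
  validate_labeled_csr(m)
  if (dir.exists(folder) &&
      file.exists(file.path(folder, matrix_files["meta"])) && !overwrite) {
    stop("folder '", folder, "' already contains a matrix; ",
         "use overwrite to replace it", call. = FALSE)
  }
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  write_lines <- function(v, f) {
    con <- file(file.path(folder, f), "wb")
    on.exit(close(con))
    writeLines(as.character(v), con, sep = "\n", useBytes = TRUE)
  }
  meta <- matrix(c(FORMAT_VERSION,
                   as.character(length(m$row_labels)),
                   as.character(length(m$col_labels)),
                   as.character(length(m$j)),
                   if (m$is_binary) "true" else "false"), nrow = 1)
  colnames(meta) <- c("format_version", "n_rows", "n_cols", "nnz", "is_binary")
  write.dcf(meta, file.path(folder, matrix_files["meta"]))
  write_lines(format(m$p, scientific = FALSE, trim = TRUE), matrix_files["p"])
  write_lines(m$j, matrix_files["j"])
  write_lines(format(m$x, scientific = FALSE, trim = TRUE), matrix_files["x"])
  write_lines(m$row_labels, matrix_files["rows"])
  write_lines(m$col_labels, matrix_files["cols"])
  store <- attr(m, "protein_index")
  if (!is.null(store)) {
    con <- file(file.path(folder, PROTEIN_STORE), "wb")
    lines <- paste(store$genome_id, store$feature, store$protein_id,
                   sep = "\t")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(folder)
}

#' Load a matrix folder
#'
#' `load_matrix()` reads a folder written by [save_matrix()] back into a
#' `labeled_csr`, reproducing every field exactly. `load_binary_matrix()`
#' returns the presence/absence view of the same folder — equivalent to
#' `binarize(load_matrix(folder))` — without ever densifying.
#'
#' @param folder Path to a matrix folder.
#' @return A `labeled_csr`; for `load_binary_matrix()`, a binary one.
#' @export
load_matrix <- function(folder) {
  if (!dir.exists(folder)) {
    stop("matrix folder not found: ", folder, call. = FALSE)
  }
  for (f in matrix_files) {
    if (!file.exists(file.path(folder, f))) {
      stop("matrix folder '", folder, "' is missing component file '", f,
           "'", call. = FALSE)
    }
  }
  meta <- read.dcf(file.path(folder, matrix_files["meta"]))
  if (!"format_version" %in% colnames(meta) ||
      meta[1, "format_version"] != FORMAT_VERSION) {
    stop("unknown matrix folder format version in '", folder, "'",
         call. = FALSE)
  }
  n_rows <- as.integer(meta[1, "n_rows"])
  n_cols <- as.integer(meta[1, "n_cols"])
  nnz <- as.numeric(meta[1, "nnz"])
  is_binary <- identical(meta[1, "is_binary"], "true")
  scan_file <- function(f, what) {
    v <- scan(file.path(folder, f), what = what, quiet = TRUE)
    v
  }
  read_labels <- function(f, n) {
    v <- readLines(file.path(folder, f), encoding = "UTF-8", warn = FALSE)
    if (length(v) != n) {
      stop("corrupt matrix folder: '", f, "' has ", length(v),
           " labels, expected ", n, call. = FALSE)
    }
    v
  }
  p <- scan_file(matrix_files["p"], numeric(0))
  j <- scan_file(matrix_files["j"], integer(0))
  x <- scan_file(matrix_files["x"], numeric(0))
  if (length(p) != n_rows + 1L || length(j) != nnz || length(x) != nnz) {
    stop("corrupt matrix folder '", folder,
         "': array lengths disagree with metadata", call. = FALSE)
  }
  m <- labeled_csr(p, j, x,
                   read_labels(matrix_files["rows"], n_rows),
                   read_labels(matrix_files["cols"], n_cols),
                   is_binary = is_binary)
  store_path <- file.path(folder, PROTEIN_STORE)
  if (file.exists(store_path)) {
    lines <- readLines(store_path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) == 0L) {
      store <- data.frame(genome_id = character(0), feature = character(0),
                          protein_id = character(0), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(parts) != 3L)) {
        stop("corrupt protein-id store in '", folder, "'", call. = FALSE)
      }
      store <- data.frame(
        genome_id = vapply(parts, `[[`, character(1), 1L),
        feature = vapply(parts, `[[`, character(1), 2L),
        protein_id = vapply(parts, `[[`, character(1), 3L),
        stringsAsFactors = FALSE)
    }
    attr(m, "protein_index") <- store
  }
  m
}

#' @rdname load_matrix
#' @export
load_binary_matrix <- function(folder) {
  binarize(load_matrix(folder))
}
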