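#' Parse hmmsearch per-domain tabular output into domain hits
#'
#' Reads the whitespace-delimited per-domain tabular output of `hmmsearch`
#' (the `--domtblout` format: one line per domain match, `#`-prefixed comment
#' lines) and returns one record per accepted match. When `hmmsearch` scans a
#' protein database with profile HMMs, the target name (column 1) is the
#' protein identifier and the query accession (column 5) is the Pfam
#' accession of the matched domain.
#'
#' The Pfam accession is truncated at the first `.` so that `PF04542.12`
#' becomes `PF04542`: domain architectures are written with unversioned
#' accessions. Alignment coordinates are taken from the envelope columns
#' (`env from` / `env to`, columns 20-21), 1-based inclusive; they are used
#' downstream only to order domains along a protein. Files ending in `.gz`
#' are read through a gzip connection.
#'
#' @param path Path to a domtblout file, plain or gzip-compressed.
#' @param max_i_evalue Optional numeric: drop matches whose independent
#'   E-value (column 13) exceeds this threshold. The default `NULL` keeps
#'   every reported per-domain line.
#' @return A data frame of domain hits with columns `protein_id`,
#'   `domain_accession`, `ali_start`, `ali_end`, `bit_score`, `i_evalue`,
#'   in file order.
#' @seealso [hits_by_protein()], [build_architecture()]
#' @export
parse_domain_hits <- function(path, max_i_evalue = NULL) {
  if (!file.exists(path)) {
    stop("hmmsearch result file not found: ", path, call. = FALSE)
  }
  con <- if (endsWith(path, ".gz")) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_data <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(is_data)
  lines <- lines[is_data]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  # we index through column 21 (env to); the description field beyond column
  # 22 may contain arbitrary whitespace and is ignored
  if (any(nf < 21L)) {
    bad <- which(nf < 21L)[1L]
    stop("parse error in ", path, " line ", lineno[bad],
         ": expected at least 21 whitespace-delimited columns, found ",
         nf[bad], call. = FALSE)
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("parse error in ", path, " line ", lineno[bad],
           ": unparseable ", what, " field '", col(k)[bad], "'",
           call. = FALSE)
    }
    v
  }
  hits <- data.frame(
    protein_id       = col(1L),
    domain_accession = sub("\\..*$", "", col(5L)),
    ali_start        = as.integer(num(20L, "envelope start")),
    ali_end          = as.integer(num(21L, "envelope end")),
    bit_score        = num(14L, "domain bit score"),
    i_evalue         = num(13L, "i-Evalue"),
    stringsAsFactors = FALSE
  )
  if (any(hits$ali_start > hits$ali_end)) {
    bad <- which(hits$ali_start > hits$ali_end)[1L]
    stop("parse error in ", path, " line ", lineno[bad],
         ": envelope start exceeds envelope end", call. = FALSE)
  }
  if (!is.null(max_i_evalue)) {
    hits <- hits[hits$i_evalue <= max_i_evalue, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

empty_hits <- function() {
  data.frame(protein_id = character(0), domain_accession = character(0),
             ali_start = integer(0), ali_end = integer(0),
             bit_score = numeric(0), i_evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Group domain hits by protein
#'
#' Splits a hit table into one data frame per protein. Proteins appear in
#' first-seen order and each bucket preserves the input row order, so every
#' input hit lands in exactly one bucket.
#'
#' @param hits A domain-hit data frame as returned by [parse_domain_hits()].
#' @return A named list of data frames, one per distinct `protein_id`.
#' @export
hits_by_protein <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    return(structure(list(), names = character(0)))
  }
  f <- factor(hits$protein_id, levels = unique(hits$protein_id))
  out <- split(hits, f)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}
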