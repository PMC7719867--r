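#' Read a genome manifest
#'
#' A manifest is the build input of the toolkit: a two-column tab-delimited
#' file mapping each unique genome identifier to the path of its hmmsearch
#' per-domain result file. The order of lines defines the row order of every
#' matrix built from the manifest.
#'
#' Lines that are empty or start with `#` are ignored. Paths are not required
#' to exist at read time; they are validated when the result files are parsed.
#'
#' @param path Path to a 2-column TSV (`genome_id`, `path`), no header, UTF-8.
#' @return A data frame with character columns `genome_id` and `path`, one row
#'   per manifest entry, in file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("g1\t/a.tbl", "g2\t/b.tbl"), tf)
#' read_manifest(tf)
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  kept_lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(genome_id = character(0), path = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- kept_lineno[which(nf < 2L)[1L]]
    stop("manifest format error: line ", bad,
         " has fewer than 2 tab-separated fields", call. = FALSE)
  }
  genome_id <- vapply(fields, `[[`, character(1), 1L)
  file_path <- vapply(fields, `[[`, character(1), 2L)
  dup <- genome_id[duplicated(genome_id)]
  if (length(dup) > 0L) {
    stop("duplicate genome id in manifest: ", dup[1L], call. = FALSE)
  }
  data.frame(genome_id = genome_id, path = file_path, stringsAsFactors = FALSE)
}
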