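#' Collapse one protein's domain hits into its domain architecture
#'
#' The domain architecture of a protein is the ordered sequence of its
#' functional domains along the sequence, written as Pfam accessions joined
#' by `_`. Order matters — the same domains in a different order can carry a
#' different function — and repeated domains are kept, not deduplicated (a
#' TcdA-like toxin carries five consecutive PF19127 units).
#'
#' Hits are sorted by ascending start coordinate; ties are broken by end
#' coordinate, then by accession (bytewise), so the string is invariant under
#' any permutation of the input rows. Overlapping hits are kept as reported.
#'
#' @param hits Domain-hit data frame for a single protein (all rows share one
#'   `protein_id`); must be non-empty.
#' @return A list with `protein_id`, `architecture` (the joined string) and
#'   `n_units` (number of domain units).
#' @examples
#' h <- data.frame(protein_id = "p1",
#'                 domain_accession = c("PF07952", "PF01742"),
#'                 ali_start = c(500L, 10L), ali_end = c(700L, 400L),
#'                 bit_score = c(50, 80), i_evalue = c(1e-10, 1e-20))
#' build_architecture(h)$architecture  # "PF01742_PF07952"
#' @export
build_architecture <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    stop("cannot build an architecture from an empty hit list", call. = FALSE)
  }
  pid <- unique(hits$protein_id)
  if (length(pid) != 1L) {
    stop("hits span multiple proteins: ",
         paste(pid, collapse = ", "), call. = FALSE)
  }
  if (any(grepl("_", hits$domain_accession, fixed = TRUE))) {
    stop("domain accession contains the reserved delimiter '_': ",
         hits$domain_accession[grepl("_", hits$domain_accession)][1L],
         call. = FALSE)
  }
  ord <- order(hits$ali_start, hits$ali_end, hits$domain_accession,
               method = "radix")
  acc <- hits$domain_accession[ord]
  list(protein_id = pid,
       architecture = paste(acc, collapse = "_"),
       n_units = length(acc))
}

#' Domain architectures of every protein in a genome
#'
#' Applies [build_architecture()] to each protein's hits. Proteins with no
#' hits never appear in hmmsearch output and therefore contribute nothing.
#' Duplicate architecture strings across proteins are retained — counting
#' happens in the matrix build.
#'
#' @param hits Domain-hit data frame for one genome (any number of proteins).
#' @return Data frame with columns `protein_id`, `architecture`, `n_units`,
#'   one row per protein with at least one hit, in first-seen protein order.
#' @export
architectures_for_genome <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    return(data.frame(protein_id = character(0), architecture = character(0),
                      n_units = integer(0), stringsAsFactors = FALSE))
  }
  buckets <- hits_by_protein(hits)
  archs <- lapply(buckets, build_architecture)
  data.frame(
    protein_id = vapply(archs, `[[`, character(1), "protein_id"),
    architecture = vapply(archs, `[[`, character(1), "architecture"),
    n_units = vapply(archs, `[[`, integer(1), "n_units"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
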