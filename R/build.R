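#' Build a genome-by-feature count matrix from a manifest
#'
#' Streams through the manifest one genome at a time, parses each hmmsearch
#' result file, maps the genome's hits to features through `feature_fn`, and
#' accumulates the counts directly in compressed sparse row form. No dense
#' `n_genomes x n_features` intermediate is ever materialized, so memory use
#' is proportional to the number of nonzero cells.
#'
#' Rows follow manifest order. Columns are all distinct features observed
#' across the manifest, in first-seen order during the sweep — deterministic
#' for a fixed manifest and inputs.
#'
#' @param manifest Data frame from [read_manifest()].
#' @param feature_fn Function mapping one genome's domain-hit data frame to a
#'   data frame with columns `protein_id` and `feature`, one row per feature
#'   occurrence. See [domain_features()] and [architecture_features()].
#' @param max_i_evalue Optional i-Evalue threshold passed to
#'   [parse_domain_hits()].
#' @param keep Logical; if `TRUE`, a protein-id store — the distinct
#'   (genome, feature, protein) associations, sorted — is attached to the
#'   result as attribute `"protein_index"` and persisted by [save_matrix()].
#'   Required later by [get_protein_ids()].
#' @return A count `labeled_csr`.
#' @seealso [build_domain_matrix()], [build_architecture_matrix()]
#' @export
build_count_matrix <- function(manifest, feature_fn, max_i_evalue = NULL,
                               keep = FALSE) {
  stopifnot(is.data.frame(manifest),
            all(c("genome_id", "path") %in% names(manifest)))
  n_genomes <- nrow(manifest)
  col_env <- new.env(hash = TRUE, parent = emptyenv())
  col_labels <- character(0)
  rows_j <- vector("list", n_genomes)
  rows_x <- vector("list", n_genomes)
  keep_tabs <- if (keep) vector("list", n_genomes) else NULL

  for (g in seq_len(n_genomes)) {
    gid <- manifest$genome_id[g]
    hits <- tryCatch(
      parse_domain_hits(manifest$path[g], max_i_evalue = max_i_evalue),
      error = function(e) {
        stop("failed to read hits for genome '", gid, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    feats <- feature_fn(hits)
    if (nrow(feats) == 0L) {
      rows_j[[g]] <- integer(0)
      rows_x[[g]] <- numeric(0)
      if (keep) keep_tabs[[g]] <- NULL
      next
    }
    new_feats <- unique(feats$feature)
    new_feats <- new_feats[!vapply(new_feats, exists, logical(1),
                                   envir = col_env, inherits = FALSE)]
    if (length(new_feats) > 0L) {
      for (k in seq_along(new_feats)) {
        assign(new_feats[k], length(col_labels) + k - 1L, envir = col_env)
      }
      col_labels <- c(col_labels, new_feats)
    }
    jj <- vapply(feats$feature, get, numeric(1), envir = col_env,
                 USE.NAMES = FALSE)
    cnt <- table(jj)
    j_row <- as.integer(names(cnt))
    ord <- order(j_row)
    rows_j[[g]] <- j_row[ord]
    rows_x[[g]] <- as.numeric(cnt)[ord]
    if (keep) {
      assoc <- unique(data.frame(genome_id = gid, feature = feats$feature,
                                 protein_id = feats$protein_id,
                                 stringsAsFactors = FALSE))
      keep_tabs[[g]] <- assoc
    }
  }

  p <- c(0, cumsum(vapply(rows_j, length, numeric(1))))
  m <- labeled_csr(p = p,
                   j = unlist(rows_j, use.names = FALSE),
                   x = unlist(rows_x, use.names = FALSE),
                   row_labels = manifest$genome_id,
                   col_labels = col_labels,
                   is_binary = FALSE)
  if (keep) {
    store <- do.call(rbind, keep_tabs[!vapply(keep_tabs, is.null, logical(1))])
    if (is.null(store)) {
      store <- data.frame(genome_id = character(0), feature = character(0),
                          protein_id = character(0), stringsAsFactors = FALSE)
    }
    ord <- order(store$genome_id, store$feature, store$protein_id,
                 method = "radix")
    store <- store[ord, , drop = FALSE]
    rownames(store) <- NULL
    attr(m, "protein_index") <- store
  }
  m
}

#' Feature extractors for the two matrix modes
#'
#' `domain_features()` maps a genome's hits to one feature occurrence per
#' domain hit (feature = Pfam accession), so a cell counts the genome's total
#' hits for that domain. `architecture_features()` maps them to one feature
#' occurrence per protein (feature = the protein's domain-architecture
#' string), so a cell counts the proteins sharing that architecture.
#'
#' @param hits Domain-hit data frame for one genome.
#' @return Data frame with columns `protein_id`, `feature`.
#' @export
domain_features <- function(hits) {
  data.frame(protein_id = hits$protein_id, feature = hits$domain_accession,
             stringsAsFactors = FALSE)
}

#' @rdname domain_features
#' @export
architecture_features <- function(hits) {
  a <- architectures_for_genome(hits)
  data.frame(protein_id = a$protein_id, feature = a$architecture,
             stringsAsFactors = FALSE)
}

#' Build the genome-by-domain count matrix
#'
#' Convenience wrapper: [build_count_matrix()] with [domain_features()].
#'
#' @inheritParams build_count_matrix
#' @return A count `labeled_csr` whose columns are Pfam accessions.
#' @export
build_domain_matrix <- function(manifest, max_i_evalue = NULL, keep = FALSE) {
  build_count_matrix(manifest, domain_features,
                     max_i_evalue = max_i_evalue, keep = keep)
}

#' Build the genome-by-architecture count matrix
#'
#' Convenience wrapper: [build_count_matrix()] with
#' [architecture_features()].
#'
#' @inheritParams build_count_matrix
#' @return A count `labeled_csr` whose columns are architecture strings.
#' @export
build_architecture_matrix <- function(manifest, max_i_evalue = NULL,
                                      keep = FALSE) {
  build_count_matrix(manifest, architecture_features,
                     max_i_evalue = max_i_evalue, keep = keep)
}
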