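#' Specification for a synthetic hmmsearch fixture
#'
#' Describes the statistical shape of a synthetic genome collection: how
#' many genomes, how large the domain vocabulary, how many proteins carry
#' hits, how many domains each protein carries and how often a domain is
#' tandem-repeated (which exercises multi-unit architectures such as the
#' clostridial toxins). Defaults are a scaled-down bacterial pan-genome:
#' tens of genomes sharing a few hundred Pfam domains, most proteins with a
#' single domain and occasional multi-domain proteins with repeats.
#'
#' @param n_genomes Number of genomes.
#' @param domain_vocab_size Size of the Pfam accession vocabulary sampled
#'   from (accessions `PF00001` ...).
#' @param mean_proteins_per_genome Poisson mean of proteins per genome.
#' @param mean_domains_per_protein Mean domain units per hit-carrying
#'   protein (>= 1; the excess over 1 is Poisson).
#' @param repeat_domain_prob Probability that a domain unit repeats the
#'   previous unit (tandem repeat) instead of being drawn fresh.
#' @param presence_density Probability that a protein carries any domain
#'   hits at all; proteins without hits never appear in hmmsearch output.
#' @param seed Integer seed; a fixed seed yields byte-identical files.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genomes = 50, domain_vocab_size = 300,
                         mean_proteins_per_genome = 80,
                         mean_domains_per_protein = 1.3,
                         repeat_domain_prob = 0.05,
                         presence_density = 0.9, seed = 1L) {
  stopifnot(n_genomes >= 0, domain_vocab_size >= 1,
            mean_proteins_per_genome > 0, mean_domains_per_protein >= 1,
            repeat_domain_prob >= 0, repeat_domain_prob <= 1,
            presence_density > 0, presence_density <= 1)
  structure(list(n_genomes = as.integer(n_genomes),
                 domain_vocab_size = as.integer(domain_vocab_size),
                 mean_proteins_per_genome = mean_proteins_per_genome,
                 mean_domains_per_protein = mean_domains_per_protein,
                 repeat_domain_prob = repeat_domain_prob,
                 presence_density = presence_density,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Write domain hits as hmmsearch per-domain tabular output
#'
#' Emits the 23-column `--domtblout` dialect consumed by
#' [parse_domain_hits()]: comment header, one line per domain match,
#' whitespace-delimited. Columns the package does not consume are filled
#' with plausible values. Numeric fields are printed with enough digits
#' that parsing the file recovers the input values exactly, provided they
#' carry at most 8 significant digits.
#'
#' @param hits Data frame with columns `protein_id`, `domain_accession`
#'   (may carry a `.N` version suffix), `ali_start`, `ali_end`, `bit_score`,
#'   `i_evalue`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  if (nrow(hits) == 0L) {
    writeLines(header, con, useBytes = TRUE)
    return(invisible(path))
  }
  ord <- seq_len(nrow(hits))  # file order == input order
  per_prot_n <- ave(rep(1L, nrow(hits)), hits$protein_id, FUN = sum)
  dom_idx <- ave(rep(1L, nrow(hits)), hits$protein_id, FUN = cumsum)
  tlen <- ave(hits$ali_end, hits$protein_id, FUN = max) + 10L
  qlen <- hits$ali_end - hits$ali_start + 1L
  query_name <- sub("\\..*$", "", hits$domain_accession)
  lines <- sprintf(
    "%s - %d %s %s %d %.8g %.8g 0.1 %d %d %.8g %.8g %.8g 0.1 1 %d %d %d %d %d 0.90 -",
    hits$protein_id, as.integer(tlen), query_name, hits$domain_accession,
    as.integer(qlen), hits$i_evalue, hits$bit_score,
    as.integer(dom_idx), as.integer(per_prot_n),
    hits$i_evalue / 10, hits$i_evalue, hits$bit_score,
    as.integer(qlen), hits$ali_start, hits$ali_end,
    hits$ali_start, hits$ali_end)
  writeLines(c(header, lines[ord]), con, useBytes = TRUE)
  invisible(path)
}

#' Generate a synthetic genome collection with ground truth
#'
#' Writes one domtblout file per genome plus a manifest TSV into `out_dir`,
#' and returns the exact ground truth the files encode: the dense
#' genome-by-domain count matrix, the dense genome-by-architecture count
#' matrix (columns in the same first-seen order the streaming builder uses),
#' and the distinct (genome, feature, protein) association tables for both
#' modes. Deterministic for a fixed seed.
#'
#' Domain segments along a protein are sequential and non-overlapping with
#' random lengths and gaps; accessions are written with a `.N` version
#' suffix to exercise version stripping.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Writable directory (created if needed).
#' @return List with `manifest` (data frame, also written to
#'   `manifest.tsv`), `manifest_path`, and `truth` — a list with
#'   `domain_counts`, `architecture_counts` (dense labeled matrices),
#'   `assoc_domain`, `assoc_architecture` (association data frames).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  vocab <- sprintf("PF%05d", seq_len(spec$domain_vocab_size))
  genome_ids <- sprintf("genome%04d", seq_len(spec$n_genomes))
  paths <- file.path(out_dir, paste0(genome_ids, ".domtblout"))

  dom_order <- character(0)
  arch_order <- character(0)
  dom_counts <- vector("list", spec$n_genomes)
  arch_counts <- vector("list", spec$n_genomes)
  assoc_dom <- vector("list", spec$n_genomes)
  assoc_arch <- vector("list", spec$n_genomes)

  for (g in seq_len(spec$n_genomes)) {
    n_prot <- stats::rpois(1, spec$mean_proteins_per_genome)
    rows <- list()
    prot_arch <- character(0)
    prot_ids <- character(0)
    for (k in seq_len(n_prot)) {
      if (stats::runif(1) > spec$presence_density) next
      pid <- sprintf("%s_p%04d", genome_ids[g], k)
      n_dom <- 1L + stats::rpois(1, spec$mean_domains_per_protein - 1)
      accs <- character(n_dom)
      accs[1L] <- sample(vocab, 1L)
      for (d in seq_len(n_dom)[-1L]) {
        accs[d] <- if (stats::runif(1) < spec$repeat_domain_prob) {
          accs[d - 1L]
        } else {
          sample(vocab, 1L)
        }
      }
      lens <- sample(50:300, n_dom, replace = TRUE)
      gaps <- sample(1:30, n_dom, replace = TRUE)
      ends <- cumsum(lens + gaps)
      starts <- ends - lens + 1L
      ev <- as.numeric(sprintf("%.3g", 10^-stats::runif(n_dom, 4, 60)))
      hit <- data.frame(
        protein_id = pid,
        domain_accession = paste0(accs, ".", sample(1:30, n_dom,
                                                    replace = TRUE)),
        ali_start = starts, ali_end = ends,
        bit_score = round(stats::runif(n_dom, 25, 800), 1),
        i_evalue = ev, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- hit
      prot_ids <- c(prot_ids, pid)
      prot_arch <- c(prot_arch, paste(accs, collapse = "_"))
    }
    hits <- if (length(rows)) do.call(rbind, rows) else NULL
    if (is.null(hits)) {
      hits <- data.frame(protein_id = character(0),
                         domain_accession = character(0),
                         ali_start = integer(0), ali_end = integer(0),
                         bit_score = numeric(0), i_evalue = numeric(0),
                         stringsAsFactors = FALSE)
    }
    write_domtblout(hits, paths[g])

    accs_stripped <- sub("\\..*$", "", hits$domain_accession)
    new_d <- setdiff(unique(accs_stripped), dom_order)
    dom_order <- c(dom_order, new_d)
    new_a <- setdiff(unique(prot_arch), arch_order)
    arch_order <- c(arch_order, new_a)
    dom_counts[[g]] <- table(accs_stripped)
    arch_counts[[g]] <- table(prot_arch)
    if (nrow(hits) > 0L) {
      assoc_dom[[g]] <- unique(data.frame(
        genome_id = genome_ids[g], feature = accs_stripped,
        protein_id = hits$protein_id, stringsAsFactors = FALSE))
      assoc_arch[[g]] <- data.frame(
        genome_id = genome_ids[g], feature = prot_arch,
        protein_id = prot_ids, stringsAsFactors = FALSE)
    }
  }

  dense_from <- function(tabs, feat_order) {
    m <- matrix(0, spec$n_genomes, length(feat_order),
                dimnames = list(genome_ids, feat_order))
    for (g in seq_len(spec$n_genomes)) {
      t <- tabs[[g]]
      if (length(t) > 0L) m[g, names(t)] <- as.numeric(t)
    }
    m
  }
  bind_assoc <- function(lst) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst) == 0L) {
      return(data.frame(genome_id = character(0), feature = character(0),
                        protein_id = character(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }

  manifest <- data.frame(genome_id = genome_ids, path = paths,
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  con <- file(manifest_path, "wb")
  if (nrow(manifest) > 0L) {
    writeLines(paste(manifest$genome_id, manifest$path, sep = "\t"), con,
               useBytes = TRUE)
  }
  close(con)
  list(manifest = manifest, manifest_path = manifest_path,
       truth = list(domain_counts = dense_from(dom_counts, dom_order),
                    architecture_counts = dense_from(arch_counts, arch_order),
                    assoc_domain = bind_assoc(assoc_dom),
                    assoc_architecture = bind_assoc(assoc_arch)))
}

#' Dense brute-force oracle over fixture ground truth
#'
#' Answers the same queries as the CSR analysis layer by exhaustive
#' computation over a dense truth matrix — the reference a relational or
#' uncompressed implementation would give. Used to validate the compressed
#' path; never used by it.
#'
#' @param dense Dense labeled count matrix (a `truth` component of
#'   [generate_fixture()]).
#' @param query One of `"core"`, `"sum_rows"`, `"sum_columns"`,
#'   `"protein_ids"`.
#' @param list_row,list_col Genome / feature labels (defaults: all).
#' @param cutoff Conservation cutoff for `"core"`.
#' @param assoc Association data frame, required for `"protein_ids"`.
#' @return A data frame shaped like the corresponding analysis function's
#'   output.
#' @export
naive_oracle <- function(dense, query = c("core", "sum_rows", "sum_columns",
                                          "protein_ids"),
                         list_row = rownames(dense),
                         list_col = colnames(dense),
                         cutoff = 0.95, assoc = NULL) {
  query <- match.arg(query)
  sub <- dense[list_row, list_col, drop = FALSE]
  switch(query,
    core = {
      counts <- colSums(sub > 0)
      frac <- counts / length(list_row)
      keep <- frac >= cutoff
      data.frame(col_name = list_col[keep],
                 genome_count = unname(counts[keep]),
                 fraction = unname(frac[keep]),
                 stringsAsFactors = FALSE, row.names = NULL)
    },
    sum_rows = data.frame(row_name = list_row,
                          row_sum = unname(rowSums(sub)),
                          stringsAsFactors = FALSE, row.names = NULL),
    sum_columns = data.frame(col_name = list_col,
                             col_sum = unname(colSums(sub)),
                             stringsAsFactors = FALSE, row.names = NULL),
    protein_ids = {
      stopifnot(!is.null(assoc))
      sel <- assoc$genome_id %in% list_row & assoc$feature %in% list_col
      out <- assoc[sel, , drop = FALSE]
      ord <- order(out$genome_id, out$feature, out$protein_id,
                   method = "radix")
      out <- out[ord, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
}

#' Random labeled binary CSR matrix
#'
#' Draws each genome's feature set independently (every feature present
#' with probability `density`) and assembles the result directly in
#' compressed form. Used for scaling studies of the query layer where the
#' matrix itself, not the hmmsearch parsing, is under test.
#'
#' @param n_rows,n_cols Matrix dimensions.
#' @param density Per-cell presence probability.
#' @param seed Integer seed.
#' @return A binary `labeled_csr`.
#' @export
random_binary_csr <- function(n_rows, n_cols, density, seed = 1L) {
  set.seed(seed)
  k <- stats::rbinom(n_rows, n_cols, density)
  rows_j <- lapply(k, function(ki) sort(sample.int(n_cols, ki)) - 1L)
  p <- c(0, cumsum(k))
  j <- unlist(rows_j, use.names = FALSE)
  if (is.null(j)) j <- integer(0)
  labeled_csr(p, j, rep(1, length(j)),
              sprintf("genome%06d", seq_len(n_rows)),
              sprintf("PF%05d", seq_len(n_cols)),
              is_binary = TRUE)
}
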