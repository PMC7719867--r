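# shared helpers: hand-built hit tables, tiny manifests, folder hashing

make_hits <- function(protein_id, accessions, starts = NULL, ends = NULL,
                      bit_score = NULL, i_evalue = NULL) {
  n <- length(accessions)
  if (is.null(starts)) starts <- seq(1L, by = 300L, length.out = n)
  if (is.null(ends)) ends <- starts + 249L
  data.frame(
    protein_id = rep_len(protein_id, n),
    domain_accession = accessions,
    ali_start = as.integer(starts),
    ali_end = as.integer(ends),
    bit_score = if (is.null(bit_score)) round(50 + 2 * (seq_len(n) - 1), 1)
                else bit_score,
    i_evalue = if (is.null(i_evalue))
      as.numeric(sprintf("%.3g", 10^-(10 + seq_len(n)))) else i_evalue,
    stringsAsFactors = FALSE
  )
}

# write one domtblout per genome plus manifest; genomes is a named list of
# hit data frames
write_genome_set <- function(genomes, dir = tempfile("gset")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(genomes))
  for (i in seq_along(genomes)) {
    paths[i] <- file.path(dir, paste0(names(genomes)[i], ".domtblout"))
    write_domtblout(genomes[[i]], paths[i])
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  writeLines(paste(names(genomes), paths, sep = "\t"), manifest_path)
  manifest_path
}

# stable digest of every regular file in a folder
folder_digest <- function(folder) {
  files <- sort(list.files(folder, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) {
    paste(c(basename(f), readLines(f, warn = FALSE)), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
}

expect_same_csr <- function(a, b) {
  expect_equal(a$p, b$p)
  expect_equal(a$j, b$j)
  expect_equal(a$x, b$x)
  expect_identical(a$row_labels, b$row_labels)
  expect_identical(a$col_labels, b$col_labels)
  expect_identical(a$is_binary, b$is_binary)
}

# dense reconstruction used as the independent identity oracle
reconstruct_dense <- function(p, j, x, n_rows, n_cols) {
  d <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    idx <- if (p[i + 1] > p[i]) (p[i] + 1):p[i + 1] else integer(0)
    d[i, j[idx] + 1L] <- x[idx]
  }
  d
}
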