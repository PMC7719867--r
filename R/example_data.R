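#' Packaged synthetic toxin example
#'
#' The package ships two tiny synthetic hmmsearch result files (under
#' `extdata/toxin_synthetic/`) modelled on well-known clostridial toxin
#' domain layouts: a *Clostridioides difficile*-like genome whose proteins
#' carry the TcdB architecture
#' `PF12918_PF12919_PF11713_PF12920_PF19127_PF19127` and the TcdA
#' architecture with five trailing PF19127 repeats, and a *Clostridium
#' botulinum*-like genome with the BoNT architecture
#' `PF01742_PF07952_PF07953_PF07951`. Both genomes also carry a sigma-factor
#' region 2 domain (PF04542). The files are hand-built stand-ins for real
#' hmmsearch output, not derived from real sequences.
#'
#' Because a manifest stores file paths, the helper writes a fresh manifest
#' into `dir` pointing at the installed copies of the files.
#'
#' @param dir Directory for the manifest (created if needed).
#' @return Path to the written manifest TSV.
#' @examples
#' mf <- toxin_example_manifest(tempfile("tox"))
#' m <- build_architecture_matrix(read_manifest(mf), keep = TRUE)
#' get_columns(m)
#' @export
toxin_example_manifest <- function(dir = tempfile("toxin_example")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(cdiff = "clostridioides_synthetic.domtblout",
             cbot = "botulinum_synthetic.domtblout")
  paths <- vapply(files, function(f) {
    p <- system.file("extdata", "toxin_synthetic", f, package = "domatrix")
    if (!nzchar(p)) stop("packaged example data not found", call. = FALSE)
    p
  }, character(1))
  manifest_path <- file.path(dir, "manifest.tsv")
  con <- file(manifest_path, "wb")
  writeLines(paste(names(paths), paths, sep = "\t"), con, useBytes = TRUE)
  close(con)
  manifest_path
}
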