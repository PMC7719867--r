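Package: domatrix
Title: Compressed Sparse Genome-by-Domain Matrices for Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds labeled compressed sparse row (CSR) matrices of genomes by
    Pfam protein functional domains, or by whole-protein domain architectures,
    from per-genome HMMER hmmsearch per-domain tabular results. Provides fast
    query utilities on the compressed representation: row and column label
    access, row- and column-wise summation, core-feature (conservation
    cut-off) calculation, and retrieval of the protein identifiers behind any
    genome/feature cell, together with a versioned on-disk matrix folder
    format, a command-line interface, and a synthetic hmmsearch fixture
    generator with a dense brute-force oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
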