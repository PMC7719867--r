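# domatrix

Compressed sparse genome-by-domain matrices for comparative genomics.

## The problem

Annotating every protein of every genome in a large bacterial collection
with Pfam functional domains (profile-HMM hits from `hmmsearch`) yields a
natural data structure: a matrix with one row per genome and one column per
feature, where a feature is either a single Pfam domain (e.g. `PF04542`,
the region 2 domain of the primary sigma factor RpoD) or a whole-protein
**domain architecture** — the ordered, underscore-joined sequence of
domains along one protein, such as the *Clostridioides difficile* TcdB
toxin architecture `PF12918_PF12919_PF11713_PF12920_PF19127_PF19127`.
Order matters and repeats are kept: the TcdA analogue carries five
consecutive `PF19127` units.

Across thousands of genomes this matrix is enormous and mostly zeros.
`domatrix` stores it in **compressed sparse row (CSR)** form: the dense
matrix is first reduced to coordinate triples (row, column, value) for the
nonzero cells only, and the sorted row vector is then compressed into
adjacent pairs of index pointers `P`, so that row *i*'s entries occupy
positions `P[i]..P[i+1]-1` of the column-index and value arrays. The whole
collection fits in RAM and every per-genome query is an O(1) row slice.

On top of the container the package provides the query layer a
screening pipeline needs:

* `cal_core()` — core features at a conservation cutoff (default 95%,
  boundary inclusive: a feature in exactly 19 of 20 queried genomes is
  core). The comparison is exact-rational, immune to the floating-point
  trap that `0.95 * 20 > 19`.
* `sum_rows()` / `sum_columns()` — count or presence mass per genome or per
  feature over arbitrary label subsets (e.g. per-genome toxin copy number).
* `get_protein_ids()` — the protein accessions behind any genome/feature
  cells, from a store written at build time (`keep = TRUE` / `-k`).

A synthetic fixture generator (`generate_fixture()`) emits valid
`hmmsearch --domtblout` files with exact ground truth, and a dense
brute-force oracle (`naive_oracle()`) validates every compressed-path
result.

## Worked example: screening for clostridial toxins

The package ships two tiny synthetic hmmsearch result files modelled on a
*C. difficile*-like and a *C. botulinum*-like genome:

```r
library(domatrix)

manifest <- read_manifest(toxin_example_manifest())
arch <- build_architecture_matrix(manifest, keep = TRUE)
arch
#> labeled_csr: 2 genomes x 4 features, 5 stored values (counts)

tox <- c(tcdB = "PF12918_PF12919_PF11713_PF12920_PF19127_PF19127",
         bont = "PF01742_PF07952_PF07953_PF07951")
sum_columns(arch, list_col = unname(tox))
#>                                          col_name col_sum
#> 1 PF12918_PF12919_PF11713_PF12920_PF19127_PF19127       1
#> 2                 PF01742_PF07952_PF07953_PF07951       1

get_protein_ids(arch, list_col = unname(tox))
#>   genome_id                                         feature     protein_id
#> 1      cbot                 PF01742_PF07952_PF07953_PF07951 bont_like_p001
#> 2     cdiff PF12918_PF12919_PF11713_PF12920_PF19127_PF19127 tcdB_like_p001

dom <- binarize(build_domain_matrix(manifest))
cal_core(dom, cutoff = 0.95)
#>   col_name genome_count fraction
#> 1  PF04542            2        1
#> 2  PF04545            2        1
```

Each genome carries one copy of its toxin architecture (`col_sum`), the
protein behind each hit is recovered by id, and the sigma-factor domain
`PF04542` is core (present in 100% of the two genomes) while the
toxin architectures are not.

The same builds run from the shell:

```sh
Rscript inst/cli/domatrix.R build-architecture -i manifest.tsv -o arch_fol -k
Rscript inst/cli/domatrix.R core -m arch_fol --cutoff 0.95
```

Matrix folders are versioned plain text (metadata, three array files, two
label indexes, optional protein-id store) and are byte-identical across
reruns of the same inputs.

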