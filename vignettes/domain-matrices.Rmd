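---
title: "Genome-by-domain matrices: model, compression, and queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-by-domain matrices: model, compression, and queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domatrix)
```

## The data model

A collection of annotated genomes is represented as a matrix $M$ with one
row per genome and one column per *feature*. Two feature spaces are
supported:

* **Functional domains.** Each column is a Pfam accession; cell
  $M_{gf}$ is the total number of per-domain `hmmsearch` matches of domain
  $f$ across all proteins of genome $g$.
* **Domain architectures.** Each column is a whole-protein architecture
  string: the protein's domain accessions sorted by ascending start
  coordinate and joined with `_`. Cell $M_{gf}$ counts the proteins of
  genome $g$ whose architecture equals $f$. Order is semantic (the same
  domains in a different order can mean a different function) and repeats
  are kept — a TcdA-like toxin contributes
  `..._PF19127_PF19127_PF19127_PF19127_PF19127`.

A binary view ($\operatorname{sign} M$) encodes presence/absence and is
the substrate of conservation analysis: feature $f$ is **core** for a
queried genome set $G$ at cutoff $c$ when

$$\frac{|\{g \in G : M_{gf} > 0\}|}{|G|} \;\ge\; c,$$

with default $c = 0.95$ and an inclusive boundary (19 of 20 genomes is
core at 95%).

## Compression

$M$ is huge and mostly zero, so it is never stored dense. Construction
produces the compressed sparse row form in two conceptual steps:

1. **Coordinate transformation** (`dense_to_coo()`): only the nonzero
   cells survive, as parallel vectors of row index, column index and
   value, in row-major order.
2. **Row compression** (`compress_rows()`): the sorted row vector is
   replaced by adjacent index-pointer pairs $P$ of length $n_{rows}+1$,
   where $P_{i+1}-P_i$ is the number of stored entries of row $i$.

The builders (`build_domain_matrix()`, `build_architecture_matrix()`)
stream one genome at a time — parse its hmmsearch file, tally its
features, append one compressed row — so peak memory is proportional to
the number of nonzeros, never to $n_{rows} \times n_{cols}$. Column
identity is assigned in first-seen order during the manifest sweep, which
keeps the build single-pass and makes the output deterministic for a fixed
manifest and inputs.

## Input conventions

* **Manifest:** 2-column TSV of unique genome ids and hmmsearch result
  paths; duplicate ids are an error; line order fixes matrix row order.
* **Hit files:** the per-domain tabular output of `hmmsearch`
  (`--domtblout`), plain or gzipped, with the protein as target and the
  Pfam profile as query. The envelope coordinates (columns 20–21) order
  domains along the protein; they are used only for ordering, so any
  consistently chosen coordinate pair would give the same architectures
  unless two hits interleave differently at envelope vs alignment level.
  Ties on start are broken by end coordinate, then bytewise by accession,
  making the architecture string invariant to input permutation.
  Overlapping hits are kept as reported; no overlap resolution is applied.
* **Accession versions** are stripped at the first `.` (`PF04542.12` →
  `PF04542`), since architecture strings are written unversioned. The
  underscore is a reserved delimiter and is rejected inside accessions.
* **Hit filtering:** by default every reported per-domain line is counted;
  `max_i_evalue` (CLI `--max-i-evalue`) optionally drops weak matches by
  independent E-value. No threshold is applied silently.

## On-disk format

A matrix folder holds a `metadata.dcf` (format version, shape, nonzero
count, binary flag), three newline-delimited array files (`indptr.txt`,
`indices.txt`, `values.txt`), two label files (`rows.txt`, `cols.txt`),
and optionally `proteins.tsv`, the sorted (genome, feature, protein)
store written by `keep` builds. Plain decimal text was chosen over a
binary encoding deliberately: it is portable across integer widths and
endianness, diff-able, and byte-deterministic (no timestamps), and the
round-trip contract — `load_matrix(save_matrix(m))` reproduces every
field exactly — is what defines conformance. Counts are canonical on
disk; the binary matrix is derived at load time (`load_binary_matrix()`)
without densifying.

## Numerical choices

* **Exact conservation boundary.** `cutoff * n` overshoots in floating
  point (`0.95 * 20 = 19.000000000000004`), which would silently drop a
  feature present in exactly 19/20 genomes. `cal_core()` therefore
  compares `count * den >= num * n_queried` after writing the cutoff as a
  reduced fraction `num/den` with `den` dividing $10^6$; all products stay
  far below $2^{53}$, so the comparison is integer-exact for any cutoff
  with at most six decimal places.
* **Denominators** are the size of the queried genome list, not the total
  row count, so subsetting genomes re-scopes "core" to that subset;
  genomes with zero hits still occupy rows and count in denominators.
* **Count vs binary.** `cal_core()` refuses a count matrix rather than
  thresholding it, because a count cell of 5 would otherwise contribute 5
  presences; conservation analysis is routed explicitly through the binary
  load path.
* **Column aggregation** uses a single `tabulate()` pass over the column
  indices for binary matrices and `rowsum()` on stored values otherwise;
  whole-matrix queries read the index arrays directly instead of
  materializing a row-slice index vector.

## The synthetic generator

`generate_fixture()` emulates the statistical shape of a pan-genome
annotation: `n_genomes` genomes, a Poisson number of proteins each, a
protein carrying hits with probability `presence_density`, `1 + Poisson`
domain units per hit-carrying protein, tandem repeats with probability
`repeat_domain_prob`, and sequential non-overlapping coordinates. Defaults
(50 genomes, 300-domain vocabulary, ~80 proteins/genome, 1.3 domains per
protein, 5% repeats, 0.9 presence) are a deliberately scaled-down
bacterial collection: large enough to exercise sparsity, multi-domain
architectures and empty rows, small enough that the exhaustive dense
oracle remains cheap.

Two aspects of real data are *not* emulated: domains are drawn uniformly
from the vocabulary, so there is no core/accessory frequency spectrum (a
uniformly random collection typically has **no** 95%-core features, unlike
a real species collection where ribosomal and sigma-factor domains are
core), and scores/E-values are arbitrary plausible numbers, not emission
probabilities. Passing equivalence tests therefore demonstrates
correctness of the matrix algebra and bookkeeping on data of the right
shape, not biological realism of the inputs. The packaged toxin example
(`toxin_example_manifest()`) complements this with hand-built synthetic
genomes whose architectures reproduce the well-known TcdA/TcdB and BoNT
domain layouts.

`naive_oracle()` answers core/sum/protein-id queries by exhaustive
computation over the dense truth matrix; every compressed-path result is
required to match it exactly, on randomized fixtures and query subsets.

## Scaling measurements

The scaling check times `cal_core()` over whole-matrix queries on random
binary matrices of 100, 1,000 and 10,000 genomes by 2,000 features at 40%
per-genome presence — wide, row-dense matrices, mirroring collections in
which each genome carries a large fraction of the observed domain
vocabulary. CPU time (`proc.time()` user time, after warm-up calls) is
averaged over repeated calls; the log-log slope across the three sizes is
expected near 1 (the query touches each stored entry once), and the
compressed path is compared against the dense oracle at the largest size.
Problem sizes were chosen so the whole suite runs in tens of seconds on a
single core; at 100 genomes a fixed per-query cost (label resolution,
result assembly) still contributes visibly, which biases the measured
slope slightly below 1.

## Known limitations

* In-memory indices use R integer vectors, so a single matrix is limited
  to fewer than $2^{31}$ nonzeros; the text serialization itself is
  width-agnostic.
* No sparse linear algebra beyond the provided queries (no products,
  no CSC view); the container is purpose-built for label-indexed row/column
  aggregation.
* `hmmscan` output and human-readable `hmmsearch` output are not parsed;
  only the per-domain tabular dialect is supported.
* The protein-id store records distinct (genome, feature, protein)
  associations; per-hit multiplicity within one protein is recoverable
  from the raw keep file (`raw_results.tsv`), not from the store.
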