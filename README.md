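# regstore

A desk-scale relational store for regulatory genomics: named datasets
of **areas** (ChIP regions, histone marks, open chromatin, conserved
segments, promoter predictions) and **motif instances** (scored,
stranded PWM hits), with per-user access control, dataset-level
analysis procedures whose results are stored back and memoised, and a
thin command-line interface.  It is aimed at analysts who want
intersections, gene assignments and motif scans of private data
*alongside* shared public data, with reproducible, queryable results —
without standing up a database server.

## What it computes

**Sweep-line intersections.**  All intervals go into a list *W* sorted
by left end; an active set *S* keeps the intervals spanning the sweep
position.  For each interval *K* drawn from *W*, the intervals of *S*
that end before *K* starts are expired and the rest each overlap *K*,
so all *k* overlapping pairs among *n* intervals are reported in
O(*n* log *n* + *k*).  Overlap means ≥ 1 shared base in 1-based
inclusive coordinates; results are validated against a brute-force
all-pairs oracle.

**TSS-flank gene mapping.**  An area maps to a gene iff it overlaps
the symmetric window [tss − F, tss + F] (default F = 10 kb).

**Motif scanning with exact P-values.**  A window w₁…w_L scores
`s(w) = Σᵢ log( p_pwm(i, wᵢ) / p_bg(wᵢ | wᵢ₋₁) )` against a
first-order Markov background fitted on both strands.  The null law of
s is computed exactly by dynamic programming over (previous letter,
discretised score) states; `score_to_pvalue()` converts scores to
P(Score ≥ s), and instances are called at P < 1e-4 on both strands.

**Conserved non-coding segments.**  Sliding windows of 100 reference
bases at ≥ 75% identity over a pairwise alignment, unioned into
maximal segments, exonic segments excluded; plus exact-duplicate
removal and an inclusive [100, 5000] bp length filter for net
alignment features.

Every dataset-level result is written into the store
(`area_intersection`, `motif_intersection`, `area_gene_map`) and the
(procedure, dataset-pair) job is memoised, so nothing is recomputed or
duplicated.  Datasets carry owner/reader grants; `make_public()` is
irrevocable and public datasets cannot be deleted; a stored result is
visible to a user exactly when every dataset it references is.

## Worked example

```r
library(regstore)
store <- regstore()

# two area datasets owned by user "ana"
d1 <- create_dataset(store, "ana", "H3K4me3 peaks", "Histone", "H3K4me3",
                     attributes = c(cell_type = "K562"))
d2 <- create_dataset(store, "ana", "DNase peaks", "Open Chromatin", "DNase1")
add_areas(store, "ana", d1, tibble::tibble(
  seq_region = "chr1", start = c(39500, 52000, 80000), end = c(41000, 53500, 81000)))
add_areas(store, "ana", d2, tibble::tibble(
  seq_region = "chr1", start = c(40800, 52900), end = c(42200, 54100)))

intersect_dataset_pairs(store, "ana", list(c(d1, d2)))
#> # A tibble: 1 × 4
#>   dataset1_id dataset2_id status n_new
#> 1           1           2 new        2
intersect_dataset_pairs(store, "ana", list(c(d2, d1)))   # memoised, unordered pair
#> 1           2           1 already_done     0

genes <- tibble::tibble(gene_id = "G1", name = "BDNF", seq_region = "chr1",
                        strand = "+", tss = 50000)
map_areas_to_genes(store, "ana", c(d1, d2), genes)
#> [1] 4        # four areas fall in the ±10 kb flank of the TSS

# scan a 100 kb sequence with a planted consensus site inside a peak
set.seed(42)
chr1 <- paste(sample(c("A","C","G","T"), 100000, replace = TRUE), collapse = "")
substr(chr1, 52950, 52959) <- "TGACGTCATC"
m <- matrix(0, 10, 4, dimnames = list(NULL, c("A","C","G","T")))
m[cbind(1:10, match(strsplit("TGACGTCATC", "")[[1]], colnames(m)))] <- 1
scan_genome(store, "ana", c(chr1 = chr1), pwm(m, "CREB_like", pseudocount = 0))
#>   dataset_id motif_id  n_instances
#> 1          3 CREB_like           1

rep <- flank_report(store, "ana", "BDNF", genes)
rep
#> <flank_report> gene BDNF (G1) chr1:40000-60000
#>   areas: 4   motifs intersecting areas: 1
tidy(rep)
#> # A tibble: 5 × 7
#>   kind     id dataset_id seq_region start   end strand
#> 1 area      1          1 chr1       39500 41000 <NA>
#> 2 area      2          1 chr1       52000 53500 <NA>
#> 3 area      4          2 chr1       40800 42200 <NA>
#> 4 area      5          2 chr1       52900 54100 <NA>
#> 5 motif     1          3 chr1       52950 52959 +
```

Reading the output: the two peak datasets share 2 overlapping pairs;
4 of the 5 areas fall inside the ±10 kb flank of the gene's TSS; the
scan calls exactly the planted site (P = 9.5 × 10⁻⁷ < 10⁻⁴ under the
background), and the flank report keeps only motifs that intersect a
reported area — here the planted site, which sits inside the
[52900, 54100] DNase peak.  `autoplot(rep)` draws the same content as
a one-lane-per-dataset track plot, and `write_flank_report(rep, path)`
emits the TSV rendering.

The same operations are scriptable from a shell through the bundled
CLI (`inst/cli/regstore.R`), e.g.

```sh
Rscript inst/cli/regstore.R load --user ana --store store.json \
    --file peaks.bed --type 'test area' --class 'test class'
Rscript inst/cli/regstore.R intersect --user ana --store store.json --all
Rscript inst/cli/regstore.R report --user ana --store store.json \
    --gene BDNF --genes genes.tsv
```

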