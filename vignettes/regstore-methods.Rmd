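---
title: "Methods: the models and algorithms behind regstore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the models and algorithms behind regstore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regstore)
```

## What the package models

`regstore` is a desk-scale relational store for regulatory genomics.
Its unit of organisation is the *dataset*: a named, typed collection of
either **areas** (generic regulatory intervals — ChIP regions, histone
marks, open chromatin, conserved segments, promoter predictions) or
**motif instances** (scored, stranded occurrences of a
transcription-factor binding motif).  Three families of dataset-level
procedures operate on the store:

1. **intersections** — area–area and area–motif overlap joins computed
   with a sweep-line algorithm;
2. **gene mapping** — assignment of areas to genes through symmetric
   ±10 kb windows around transcription start sites;
3. **motif scanning** — genome-wide PWM scanning with exact P-value
   calibration under a first-order Markov background.

Every result is written back into the store and memoised, so a
completed (procedure, dataset-pair) job is never recomputed and stored
results are never duplicated.  A conservation module calls conserved
non-coding segments from pairwise alignments, producing area datasets.

All coordinates inside the package are **1-based inclusive** (the
Ensembl convention).  BED input/output converts exactly once at the I/O
boundary (`start = chromStart + 1`, `end = chromEnd`) and nowhere else.

## The store and its access model

The store is a lightweight in-memory relational database: one tibble
per table (`dataset`, `dataset_attr`, `area`, `motif`,
`area_intersection`, `motif_intersection`, `area_gene_map`,
`access_grant`, `job_registry`), persisted as a single JSON file.  This
gives a serverless, text-only artefact with an exactly reproducible
byte representation — which is also how the package *tests* its own
idempotency guarantee: re-running a completed procedure must leave the
serialized store byte-identical.

Access control is per (dataset, user) with two levels. An **owner** can
do anything with the data and manage other users' access; a **reader**
can see but not modify.  Three rules shape the lifecycle:

* *Publication is irrevocable.*  `make_public()` has no inverse — the
  API deliberately contains no unpublish operation — and a public
  dataset can never be deleted.
* *Deletion cascades.*  Deleting a dataset removes its features, every
  stored intersection and gene-map row referencing them, its grants,
  attributes and job-registry entries, so the store never holds a
  dangling reference (`audit_store()` verifies this).
* *Every dataset keeps at least one owner.*  Revoking — or downgrading,
  which is a revoke-and-regrant — the sole owner is refused.  The
  downgrade case matters: without it a re-grant at reader level could
  silently orphan a dataset, which randomized lifecycle testing
  surfaced immediately.

Result visibility is the **conjunction** of dataset access: an
intersection row is visible to a user exactly when they can read both
referenced datasets; consequently results computed on private data
become public automatically when the last private member is published.

The anonymous identity is the reserved user name `"public"`: it can
hold no grants and sees exactly the public datasets.

## The sweep-line intersection engine

All intersection and mapping procedures share one core algorithm.  Per
chromosome, every interval is placed in a working list `W` sorted by
left end (ties broken by right end, then feature id, making output
deterministic).  An active set `S` holds the intervals whose span
reaches the current sweep position.  For each interval `K` taken from
`W` in order: intervals in `S` ending before `K` starts are expired,
then every remaining member of `S` overlaps `K`, so the pairs
`S × {K}` are reported, and `K` joins `S`.  This enumerates all `k`
overlapping pairs among `n` intervals in `O(n log n + k)` and touches
each non-overlapping pair never.

Design choices:

* **Overlap predicate**: at least one shared base in 1-based inclusive
  coordinates.  Adjacent intervals (`[100,200]`, `[201,300]`) do not
  overlap; a zero-length overlap cannot be expressed in inclusive
  coordinates.  This matches the default semantics of the standard
  interval-intersection tools the field treats as gold standard.
* **Strand is ignored** for intersections.
* The two-set join runs as a *single* sweep over the merged,
  dataset-tagged list with cross-tag reporting, so the pairwise,
  all-pairs, one-vs-all and area–motif variants are all the same code
  path.  Self-joins suppress (x, x) pairs.
* Stored area–area records are canonically oriented (smaller dataset id
  first), and the job registry treats the pair as unordered, so
  `(d1, d2)` and `(d2, d1)` are one job.
* Chromosome names match by exact string equality; no `"chr"` prefix
  normalisation is attempted.
* Beyond the feature ids, the stored record keeps the overlap span
  `[max(starts), min(ends)]` — cheap to compute during the sweep and
  convenient for downstream windowed queries.

Correctness is established against a brute-force all-pairs oracle (a
vectorised quadratic scan, sharing no code with the sweep) on random
fixtures up to 10^4 intervals over 2–5 chromosomes, with exact set
equality required, plus an external cross-check against
`IRanges::findOverlaps()`.

## Gene mapping

`tss_flank()` builds the window `[max(1, tss − F), tss + F]` with
`F = 10000` bp by default.  The window is symmetric and
strand-independent; for minus-strand genes the annotation must already
carry the strand-correct TSS coordinate.  Both window edges are
inclusive, consistent with the package-wide coordinate convention.
`map_areas_to_genes()` is implemented as a sweep of the areas against
the flank intervals and validated against an independent double-loop
oracle at 200 genes × 2000 areas.

The annotation contract is **one row per gene with a single TSS**.
Genes with multiple transcripts have multiple start sites; callers who
want per-transcript windows supply transcripts as rows.  This is a
documented limitation, not a hidden heuristic.

`flank_report()` reproduces the classic per-gene content view: stage 1
collects the visible areas of the selected dataset types inside the
window; stage 2 keeps only those motif instances from the selected
motif datasets that overlap at least one stage-1 area.  An empty stage
1 therefore forces an empty motif list.  The report renders as TSV
(`write_flank_report()`), a tidy tibble (`tidy()`), or a simple track
plot (`autoplot()`) — one lane per dataset, rectangles at feature
spans; a content overview, not a genome-browser rendering.

## Motif scanning and P-value calibration

### Model

A motif of length `L` is a position-weight matrix; a window
`w = w_1…w_L` scores

$$ s(w) \;=\; \sum_{i=1}^{L} \log \frac{p_{\mathrm{pwm}}(i, w_i)}{p_{\mathrm{bg}}(w_i \mid w_{i-1})} $$

in natural-log units, i.e. the log-likelihood ratio of the window
under the motif versus a **first-order Markov background**.  The first
position is scored against the background's initial (marginal) letter
distribution; each later position conditions on the previous reference
letter.

The background is fitted by dinucleotide counting over the input
sequences **and their reverse complements**, so the marginals are
complement-symmetric exactly and the transition matrix approximately
(row normalisation divides by different letters' marginals, which
differ by sampling noise; the count matrix itself is exactly
symmetric).  N-containing dinucleotides are skipped.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 0.01 | total pseudocount per PWM column, spread proportionally to the background marginals; 0 gives hard zeros (`−Inf` weights, windows never called) |
| `p_threshold` | 1e-4 | instances are called at `p < p_threshold`, strictly |
| `bin_width` | 0.01 | score discretisation in nats |
| `flank_bp` | 10000 | gene-mapping window half-width |

### Exact score distribution

`score_distribution()` computes the law of `s(W)` for a random window
drawn from the background chain started at its marginal distribution,
by dynamic programming over states (previous letter, accumulated score
bin).  Per-position weights are rounded to multiples of `bin_width`
and the DP propagates mass through the 16 letter transitions per
position, so the result is *exact up to the discretisation*: total
error at most `L · bin_width` in score, far below the resolution
needed at `P = 1e-4` for realistic `L ≤ 30`.  Windows containing a
`−Inf` weight contribute their probability to a sentinel below every
finite bin; `score_to_pvalue()` returns 1 at or below the support, 0
above it, and the bin's tail mass in between.

One numerical subtlety is worth stating because it dictated the
scanner's design: the DP discretises **per position** and sums the
rounded indices; rounding the *total* score once is a different
discretisation, and the two can differ by up to `L/2` bins.  The
scanner therefore accumulates the same per-position rounded indices as
the DP (they are carried in the distribution object), so a scanned
window's P-value is looked up in exactly the calibration that defined
it.  Calibration correctness is tested by exhaustive `4^L` word
enumeration (an independent oracle) for `L ≤ 8`: exact agreement under
the shared discretisation, and agreement within the mass of the
`±L·bin_width` band against the unbinned law.  A closed-form anchor is
also asserted: a consensus-only length-5 motif under the uniform
background has `P(max score) = 4⁻⁵`.

The distribution assumes every window starts from the chain's marginal
distribution.  Windows tile the genome densely, so start-position
boundary effects are negligible; this is the standard approximation
and it is documented rather than corrected.

### Scanning

`scan_sequences()` scores every window of both strands (reverse-strand
hits are reported in forward coordinates with a strand flag), skips
windows containing N, and calls instances at `p < p_threshold`.
`scan_genome()` wraps this per PWM, storing one motif dataset per
matrix with attributes `motif_id`, `library_tag` and `threshold`.
When no background is supplied it is fitted from the scanned sequences
themselves.  Overlapping instances of the same motif are all reported;
no merging is attempted.  JASPAR and TRANSFAC count-matrix text
formats are read natively.

## Conserved-segment calling

Input is a pairwise alignment (two equal-length gapped strings, no
gap–gap columns) with the reference anchored at a genomic offset.  A
window of exactly `min_length` **reference bases** (default 100 nt)
slides along the alignment; it qualifies when matched columns /
`min_length` ≥ `min_identity`% (default 75%).  Gaps in the reference
are excluded from the base count; gaps in the alternative sequence
count as mismatches; N never matches.  Qualifying windows are unioned
into maximal segments, the segment identity is recomputed over the
full span, and segments overlapping an exon are removed whole
(`exon_action = "remove"`, the conservative reading — trimming could
leave sub-threshold fragments; `"trim"` is available and re-filters
the pieces by `min_length`).

Two documented consequences of the window-level criterion:

* a unioned segment's recomputed identity can fall slightly below
  `min_identity` even though every window inside it passes; such
  segments are kept, with the recomputed identity recorded;
* lowering `min_identity` can only grow the called set, but lowering
  `min_length` has **no such guarantee**: a qualifying long window
  whose matches are concentrated at its ends may contain no qualifying
  shorter window.  (A 100-base window with 40 matches at each end
  passes at 80%, while every 60-base sub-window is at ≤ 67%.)  Only
  the identity direction is asserted as an invariant.

`dedup_segments()` collapses exact-coordinate duplicates — as arise
when overlapping gene flanks are aligned independently — and
`filter_by_length()` retains features with inclusive length in
`[100, 5000]` bp by default, the filter applied to net-alignment
features on import.  "Between 100 and 5000" is read as inclusive
bounds; both are overridable.

A small Needleman–Wunsch global aligner (`match +1 / mismatch −1 /
gap −2`, deterministic tie-break diagonal > up > left) is included
solely to build test alignments; production alignments come from
outside.  It is quadratic in time and memory and intended for
fixture-scale sequences up to a few kb.

## The synthetic fixture generator

`generate_fixture()` builds, deterministically under a seed: a
uniform-random genome (default two 100 kb chromosomes) with consensus
words planted at non-overlapping forward-strand positions (default one
10-mer, 20 copies); a gene annotation with uniform TSSs (200 genes);
and random area datasets (two datasets of 1000 intervals, lengths
1–500).  A truth table records every planted position and every
cross-dataset overlap, so downstream expectations are exact by
construction.  The generator saves and restores the caller's RNG
state.

What the fixtures emulate: interval densities high enough to exercise
large active sets in the sweep; planted signal recoverable at the
1e-4 threshold; a background with known composition.  What they do
**not** emulate: real genomes' repeat structure, GC heterogeneity and
higher-order composition; clustered rather than uniform features; and
real motifs' information-content profiles.  Passing tests demonstrate
algorithmic correctness against oracles under controlled conditions,
not biological performance on real data.

## Problem sizes and runtime choices

The test suite validates the sweep against its quadratic oracle on 20
fixtures of 500–10 000 intervals; gene mapping at 200 genes × 2000
areas; calibration by full enumeration up to `4^8` words; planted-motif
recovery on a 100 kb genome (with the windowed naive rescan applied to
a 4 kb slice, and an exact string-matching oracle covering the full
genome — for a consensus-only matrix the two are equivalent); lifecycle
invariants over 1200 randomized operations; and I/O round-trips at
10³ records.  These sizes were chosen so the whole suite settles in a
few minutes on one core while every algorithmic path still crosses its
oracle at non-trivial scale.

## Known limitations

* The store is in-memory; it is intended for desk-scale analyses
  (10⁵–10⁶ features), not warehouse-scale precomputation.
* Only first-order backgrounds are supported for scanning.
* Motif–motif intersections are not provided (areas–areas and
  areas–motifs only), and intersections are overlap joins — no
  distance-based or reciprocal-fraction variants.
* Per-transcript TSS handling is the caller's responsibility (one row
  per window wanted).
* The tab-separated feature dialect (header-declared columns
  `seq_region, start, end, strand, score, label, weight_score,
  p_value`) is this package's own; it is not claimed byte-compatible
  with any external system's TSV.
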