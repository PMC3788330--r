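Package: regstore
Title: A Relational Store for Regulatory Genomic Features with
    Sweep-Line Intersections, Motif Scanning and Conservation Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale store of genomic regulatory features ("areas" such
    as ChIP regions, histone marks and open chromatin, and scored
    transcription-factor motif instances) organised into datasets with
    per-user access control and irrevocable publication.  Dataset-level
    procedures compute interval intersections with a sweep-line algorithm,
    map areas to genes via symmetric transcription-start-site flanks, and
    memoise completed jobs so that results are never recomputed or
    duplicated.  A genome-wide position-weight-matrix scanner calls motif
    instances on both strands using exact discretised score distributions
    under a first-order Markov background to convert scores to P-values.
    A conservation module calls conserved non-coding segments from pairwise
    alignments by sliding-window percent identity with exon exclusion, plus
    duplicate and length filtering.  Readers and writers cover BED, a
    tab-separated feature dialect, FASTA, aligned FASTA, and JASPAR and
    TRANSFAC matrix formats; a synthetic-fixture generator and a thin
    command-line interface round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
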