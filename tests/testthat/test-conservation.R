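test_that("perfect identity yields one full-length segment; uniform 50% yields none", {
  withr::local_seed(61)
  s <- random_dna_str(300)
  aln <- pairwise_alignment(s, s, ref_name = "chr5", ref_offset = 1000)
  segs <- call_conserved_segments(aln)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1000)
  expect_equal(segs$end, 1299)
  expect_equal(segs$identity_pct, 100)
  expect_equal(segs$ungapped_ref_length, 300)

  # alternating match/mismatch: 50% identity everywhere, below threshold
  ref <- strrep("AC", 200)
  alt <- strrep("AG", 200)
  aln2 <- pairwise_alignment(ref, alt)
  expect_equal(nrow(call_conserved_segments(aln2)), 0)
  expect_error(call_conserved_segments(aln, min_identity = 0),
               class = "regstore_validation")
  expect_error(pairwise_alignment("AC-", "A--"), class = "regstore_validation")
})

test_that("an embedded high-identity block is called with oracle-identical boundaries", {
  withr::local_seed(67)
  mutate_to_identity <- function(s, identity) {
    x <- strsplit(s, "")[[1]]
    n <- length(x)
    k <- round((1 - identity) * n)
    pos <- sample.int(n, k)
    swap <- c(A = "C", C = "G", G = "T", T = "A")
    x[pos] <- swap[x[pos]]
    paste(x, collapse = "")
  }
  ref <- random_dna_str(400)
  alt <- paste0(
    mutate_to_identity(substr(ref, 1, 140), 0.40),
    mutate_to_identity(substr(ref, 141, 260), 0.80),   # 120 bp at ~80%
    mutate_to_identity(substr(ref, 261, 400), 0.40)
  )
  aln <- pairwise_alignment(ref, alt, ref_name = "chr2", ref_offset = 5001)
  segs <- call_conserved_segments(aln, min_length = 100, min_identity = 75)
  cov <- oracle_conserved_coverage(ref, alt, 100, 75)
  want <- which(cov)
  expect_gt(length(want), 0)
  got <- unlist(purrr::map2(segs$start, segs$end, ~ seq(.x, .y))) - 5000
  expect_equal(sort(got), want)
  # identity over each called segment re-verified independently
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  for (i in seq_len(nrow(segs))) {
    lo <- segs$start[i] - 5000; hi <- segs$end[i] - 5000
    id <- 100 * sum(r[lo:hi] == a[lo:hi]) / (hi - lo + 1)
    expect_equal(segs$identity_pct[i], id)
  }
})

test_that("segment calling handles gaps: reference windows count only reference bases", {
  # 150 identical bases, a 10-base insertion in alt (ref gap), 150 more
  withr::local_seed(71)
  left <- random_dna_str(150); right <- random_dna_str(150)
  ref_aln <- paste0(left, strrep("-", 10), right)
  alt_aln <- paste0(left, strrep("A", 10), right)
  aln <- pairwise_alignment(ref_aln, alt_aln, ref_offset = 101)
  segs <- call_conserved_segments(aln)
  # all 300 reference bases match: one segment spanning them
  expect_equal(nrow(segs), 1)
  expect_equal(segs$ungapped_ref_length, 300)
  expect_equal(segs$identity_pct, 100)
  # alt gaps count as mismatches: deleting 30% of alt kills the call
  ref2 <- random_dna_str(200)
  alt2 <- paste0(substr(ref2, 1, 100), strrep("-", 100))
  segs2 <- call_conserved_segments(pairwise_alignment(ref2, alt2),
                                   min_length = 150)
  expect_equal(nrow(segs2), 0)
})

test_that("exon overlap removes whole segments, or trims under the config flag", {
  withr::local_seed(73)
  s <- random_dna_str(500)
  aln <- pairwise_alignment(s, s, ref_name = "chr1", ref_offset = 1)
  exons <- tibble::tibble(start = 240, end = 260)
  expect_equal(nrow(call_conserved_segments(aln, exons = exons)), 0)
  trimmed <- call_conserved_segments(aln, exons = exons, exon_action = "trim")
  expect_equal(nrow(trimmed), 2)
  expect_equal(trimmed$start, c(1, 261))
  expect_equal(trimmed$end, c(239, 500))
  # non-overlapping exon leaves the segment alone
  far <- call_conserved_segments(aln, exons = tibble::tibble(start = 900, end = 950))
  expect_equal(nrow(far), 1)
})

test_that("relaxing the identity threshold never removes called bases", {
  # (no analogous guarantee holds for min_length: a qualifying long
  # window with its matches concentrated at the ends can contain no
  # qualifying shorter window, so only min_identity is monotone)
  withr::local_seed(79)
  ref <- random_dna_str(600)
  x <- strsplit(ref, "")[[1]]
  pos <- sample.int(600, 120)
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  x[pos] <- swap[x[pos]]
  alt <- paste(x, collapse = "")
  aln <- pairwise_alignment(ref, alt)
  base_cov <- function(segs) unlist(purrr::map2(segs$start, segs$end, seq))
  strict <- base_cov(call_conserved_segments(aln, 100, 80))
  for (ident in c(75, 70, 60)) {
    loose <- base_cov(call_conserved_segments(aln, 100, ident))
    expect_true(all(strict %in% loose))
  }
})

test_that("dedup keeps exact-coordinate duplicates once and is idempotent", {
  segs <- tibble::tibble(
    seq_region = c("chr1", "chr1", "chr1"),
    start = c(100, 100, 101), end = c(400, 400, 400),
    identity_pct = c(90, 90, 88))
  d1 <- dedup_segments(segs)
  expect_equal(nrow(d1), 2)                   # 1 bp difference kept
  expect_identical(dedup_segments(d1), d1)
})

test_that("length filter retains exactly the inclusive [100, 5000] band", {
  probe <- tibble::tibble(seq_region = "chr1", start = 1,
                          end = c(99, 100, 5000, 5001))
  kept <- filter_by_length(probe)
  expect_equal(kept$end - kept$start + 1, c(100, 5000))
  expect_equal(nrow(filter_by_length(probe[0, ])), 0)
  expect_error(filter_by_length(probe, 10, 5), class = "regstore_validation")
  withr::local_seed(83)
  lens <- sample.int(8000, 500)
  feats <- tibble::tibble(seq_region = "chr1", start = 1000, end = 999 + lens)
  expect_equal(nrow(filter_by_length(feats)), sum(lens >= 100 & lens <= 5000))
})

test_that("the fixture aligner is optimal-scoring with deterministic tie-breaks", {
  # identical sequences: gap-free, score = n * match
  aln <- needleman_wunsch_fixture_aligner("ACGTACGT", "ACGTACGT")
  expect_equal(aln$ref_aln, "ACGTACGT")
  expect_equal(attr(aln, "score"), 8)
  # hand-checkable 4x3 case: one gap column
  aln2 <- needleman_wunsch_fixture_aligner("ACGT", "ACT")
  expect_equal(attr(aln2, "score"), 3 * 1 + 1 * (-2))
  expect_equal(nchar(aln2$ref_aln), 4)
  expect_equal(sum(strsplit(aln2$alt_aln, "")[[1]] == "-"), 1)
  expect_error(needleman_wunsch_fixture_aligner("", "ACGT"),
               class = "regstore_validation")

  withr::local_seed(89)
  a <- random_dna_str(200)
  b <- random_dna_str(200)
  aln3 <- needleman_wunsch_fixture_aligner(a, b)
  # independent re-scoring of the returned alignment
  ra <- strsplit(aln3$ref_aln, "")[[1]]; rb <- strsplit(aln3$alt_aln, "")[[1]]
  rescore <- sum(ifelse(ra == "-" | rb == "-", -2, ifelse(ra == rb, 1, -1)))
  expect_equal(attr(aln3, "score"), rescore)
  # beats random alignments of the same pair (crude lower-bound check)
  for (k in 1:20) {
    gaps <- sample.int(40, 1)
    ga <- paste0(a, strrep("-", gaps))
    ord <- sample(nchar(a) + gaps)
    gb <- paste(c(strsplit(b, "")[[1]], rep("-", gaps))[ord], collapse = "")
    sc <- {
      xa <- strsplit(ga, "")[[1]]; xb <- strsplit(gb, "")[[1]]
      keep <- !(xa == "-" & xb == "-")
      xa <- xa[keep]; xb <- xb[keep]
      sum(ifelse(xa == "-" | xb == "-", -2, ifelse(xa == xb, 1, -1)))
    }
    expect_gte(attr(aln3, "score"), sc)
  }
})

test_that("the fixture aligner matches Biostrings' optimal global score", {
  skip_if_not_installed("Biostrings")
  withr::local_seed(97)
  for (k in 1:3) {
    a <- random_dna_str(120)
    b <- random_dna_str(110)
    ours <- attr(needleman_wunsch_fixture_aligner(a, b), "score")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})
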