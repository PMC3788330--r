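# Conserved non-coding segment calling on pairwise alignments:
# sliding-window percent identity over reference bases, window union,
# exon exclusion, duplicate and length filtering.  Defaults follow the
# classic conserved-element criterion: windows of 100 reference
# nucleotides at >= 75% identity, exonic segments excluded.

#' Construct a pairwise alignment object
#'
#' @param ref_aln,alt_aln Equal-length gapped strings over
#'   `A,C,G,T,N,-` (reference and alternative sequence).
#' @param ref_name,alt_name Sequence identifiers; `ref_name` doubles as
#'   the reference `seq_region` of called segments.
#' @param ref_offset 1-based genomic position of the first reference
#'   base.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(ref_aln, alt_aln, ref_name = "ref",
                               alt_name = "alt", ref_offset = 1) {
  ref_aln <- toupper(ref_aln); alt_aln <- toupper(alt_aln)
  if (nchar(ref_aln) != nchar(alt_aln)) {
    abort_validation("aligned strings must have equal length")
  }
  if (nchar(ref_aln) == 0L) abort_validation("empty alignment")
  r <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  a <- strsplit(alt_aln, "", fixed = TRUE)[[1]]
  if (any(r == "-" & a == "-")) abort_validation("gap-gap column in alignment")
  structure(list(ref_name = ref_name, alt_name = alt_name,
                 ref_aln = ref_aln, alt_aln = alt_aln,
                 ref_offset = as.double(ref_offset)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$ref_name, " vs ", x$alt_name,
      ", ", nchar(x$ref_aln), " columns, ref offset ", x$ref_offset, "\n", sep = "")
  invisible(x)
}

runs_from_coverage <- function(covered) {
  if (!any(covered)) return(cbind(start = integer(0), end = integer(0)))
  d <- diff(c(0L, as.integer(covered), 0L))
  cbind(start = which(d == 1L), end = which(d == -1L) - 1L)
}

#' Call conserved segments from a pairwise alignment
#'
#' Slides a window of exactly `min_length` reference (non-gap) bases
#' along the alignment; a window qualifies when its matched columns /
#' `min_length` reach `min_identity` percent.  Gaps in the alternative
#' sequence count as mismatches; gaps in the reference are excluded
#' from the base count.  Qualifying windows are unioned into maximal
#' segments, each segment's identity is recomputed over its full span
#' (it may fall slightly below the window threshold, which is recorded
#' as-is), and segments overlapping an exon are removed (or trimmed and
#' re-filtered with `exon_action = "trim"`).
#'
#' @param alignment A [pairwise_alignment()] object.
#' @param min_length Window size in reference bases (default 100 nt).
#' @param min_identity Window identity threshold in percent, in
#'   (0, 100\] (default 75).
#' @param exons Optional tibble of exon intervals (`start`, `end`,
#'   1-based inclusive, reference genomic coordinates).
#' @param exon_action `"remove"` drops whole segments overlapping an
#'   exon; `"trim"` cuts exonic bases out and keeps the remaining
#'   pieces that still reach `min_length`.
#' @return A tibble `seq_region`, `start`, `end`,
#'   `ungapped_ref_length`, `identity_pct`.
#' @export
call_conserved_segments <- function(alignment, min_length = 100,
                                    min_identity = 75.0, exons = NULL,
                                    exon_action = c("remove", "trim")) {
  exon_action <- match.arg(exon_action)
  if (!inherits(alignment, "pairwise_alignment")) {
    abort_validation("`alignment` must be a pairwise_alignment object")
  }
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 100) {
    abort_validation("min_identity must be in (0, 100]")
  }
  if (!is.numeric(min_length) || min_length < 1) {
    abort_validation("min_length must be >= 1")
  }
  r <- strsplit(alignment$ref_aln, "", fixed = TRUE)[[1]]
  a <- strsplit(alignment$alt_aln, "", fixed = TRUE)[[1]]
  ref_pos <- which(r != "-")
  nref <- length(ref_pos)
  empty <- tibble::tibble(seq_region = character(), start = double(), end = double(),
                          ungapped_ref_length = double(), identity_pct = double())
  if (nref < min_length) return(empty)
  match_base <- r[ref_pos] == a[ref_pos] & r[ref_pos] %in% c("A", "C", "G", "T")
  cm <- c(0, cumsum(match_base))
  nw <- nref - min_length + 1
  wmatch <- cm[(1:nw) + min_length] - cm[1:nw]
  qualifies <- wmatch / min_length >= min_identity / 100
  covered <- logical(nref)
  for (i in which(qualifies)) covered[i:(i + min_length - 1)] <- TRUE

  if (!is.null(exons) && exon_action == "trim" && nrow(exons)) {
    gpos <- alignment$ref_offset + (seq_len(nref) - 1)
    for (k in seq_len(nrow(exons))) {
      covered[gpos >= exons$start[k] & gpos <= exons$end[k]] <- FALSE
    }
  }

  runs <- runs_from_coverage(covered)
  if (exon_action == "trim" && nrow(runs)) {
    runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= min_length, , drop = FALSE]
  }
  if (nrow(runs) == 0L) return(empty)
  rs <- unname(runs[, "start"]); re <- unname(runs[, "end"])
  segs <- tibble::tibble(
    seq_region = alignment$ref_name,
    start = alignment$ref_offset + rs - 1,
    end = alignment$ref_offset + re - 1,
    ungapped_ref_length = re - rs + 1,
    identity_pct = 100 * (cm[re + 1] - cm[rs]) / (re - rs + 1)
  )
  if (!is.null(exons) && exon_action == "remove" && nrow(exons)) {
    hit <- purrr::map_lgl(seq_len(nrow(segs)), function(i) {
      any(segs$start[i] <= exons$end & segs$end[i] >= exons$start)
    })
    segs <- segs[!hit, ]
  }
  segs
}

#' Collapse exact-duplicate segments
#'
#' Segments sharing identical (`seq_region`, `start`, `end`) — as arise
#' when overlapping gene flanks are aligned independently — are kept
#' once (first occurrence wins).  Idempotent.
#'
#' @param segments A tibble with at least `seq_region`, `start`, `end`.
#' @return The deduplicated tibble.
#' @export
dedup_segments <- function(segments) {
  segments |>
    dplyr::distinct(.data$seq_region, .data$start, .data$end, .keep_all = TRUE)
}

#' Retain features within a length band
#'
#' Keeps features whose 1-based inclusive length `end - start + 1` lies
#' in `[min_bp, max_bp]` (both bounds inclusive) — the filter applied
#' to net-alignment features on import.
#'
#' @param features A tibble with `start`, `end`.
#' @param min_bp,max_bp Inclusive length bounds (defaults 100 and
#'   5000 bp).
#' @return The retained rows.
#' @export
filter_by_length <- function(features, min_bp = 100, max_bp = 5000) {
  if (min_bp > max_bp) abort_validation("min_bp must be <= max_bp")
  features |>
    dplyr::filter(.data$end - .data$start + 1 >= min_bp,
                  .data$end - .data$start + 1 <= max_bp)
}

#' Global alignment for fixture construction
#'
#' A plain Needleman–Wunsch global aligner with linear gap penalty and
#' deterministic tie-breaking (diagonal over up over left), used to
#' build small test alignments for the conservation caller.  Quadratic
#' time and memory: intended for fixture-scale sequences (up to a few
#' kb).
#'
#' @param seq_a,seq_b Sequences to align (a is the reference).
#' @param match,mismatch,gap Scores (defaults +1/-1/-2).
#' @param ref_name,alt_name,ref_offset Passed to
#'   [pairwise_alignment()].
#' @return A [pairwise_alignment()] with attribute `score`.
#' @export
needleman_wunsch_fixture_aligner <- function(seq_a, seq_b, match = 1,
                                             mismatch = -1, gap = -2,
                                             ref_name = "ref", alt_name = "alt",
                                             ref_offset = 1) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) abort_validation("empty sequence")
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  F <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)          # 1 diag, 2 up (gap in b), 3 left (gap in a)
  F[, 1] <- gap * (0:n); F[1, ] <- gap * (0:m)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in 1:n) {
    srow <- ifelse(b == a[i], match, mismatch)
    for (j in 1:m) {
      d <- F[i, j] + srow[j]
      u <- F[i, j + 1] + gap
      l <- F[i + 1, j] + gap
      if (d >= u && d >= l) { F[i + 1, j + 1] <- d; P[i + 1, j + 1] <- 1L }
      else if (u >= l)      { F[i + 1, j + 1] <- u; P[i + 1, j + 1] <- 2L }
      else                  { F[i + 1, j + 1] <- l; P[i + 1, j + 1] <- 3L }
    }
  }
  ra <- character(0); rb <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L)      { ra <- c(a[i - 1L], ra); rb <- c(b[j - 1L], rb); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) { ra <- c(a[i - 1L], ra); rb <- c("-", rb); i <- i - 1L }
    else               { ra <- c("-", ra); rb <- c(b[j - 1L], rb); j <- j - 1L }
  }
  aln <- pairwise_alignment(paste(ra, collapse = ""), paste(rb, collapse = ""),
                            ref_name = ref_name, alt_name = alt_name,
                            ref_offset = ref_offset)
  attr(aln, "score") <- F[n + 1, m + 1]
  aln
}
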