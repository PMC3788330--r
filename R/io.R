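# Format readers and writers.  Internal coordinates are 1-based
# inclusive throughout the package; BED (0-based, half-open) is
# converted exactly at this boundary and nowhere else.  Readers reject
# malformed records with the offending line number rather than
# repairing them.

#' Read a BED file as areas
#'
#' Accepts BED3–BED6; `track`, `browser` and `#` comment lines are
#' skipped.  Coordinates convert as `start = chromStart + 1`,
#' `end = chromEnd`, so a 1 bp feature `chr1 9 10` becomes `[10, 10]`.
#'
#' @param path File path.
#' @return A tibble `seq_region`, `start`, `end`, `label`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3) abort_validation(paste0("BED line ", i, ": fewer than 3 fields"))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      abort_validation(paste0("BED line ", i, ": non-integer coordinates"))
    }
    if (s >= e) abort_validation(paste0("BED line ", i, ": chromStart >= chromEnd (", s, " >= ", e, ")"))
    out[[k]] <- tibble::tibble(
      seq_region = f[1], start = s + 1, end = e,
      label = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_,
      strand = if (length(f) >= 6) f[6] else NA_character_
    )
  }
  if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    seq_region = character(), start = double(), end = double(),
    label = character(), score = double(), strand = character()
  )
}

#' Write areas as BED
#'
#' The inverse conversion of [read_bed()] (`chromStart = start - 1`,
#' `chromEnd = end`); writes BED6 when any of label/score/strand is
#' present, BED3 otherwise.  `read_bed(write_bed(x))` restores the
#' coordinates exactly.
#'
#' @param areas Tibble with `seq_region`, `start`, `end` and optional
#'   `label`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(areas, path) {
  col_or_na <- function(nm, proto) {
    if (nm %in% names(areas)) areas[[nm]] else rep(proto, nrow(areas))
  }
  lab <- col_or_na("label", NA_character_)
  sco <- col_or_na("score", NA_real_)
  str <- col_or_na("strand", NA_character_)
  has_extra <- !all(is.na(lab)) || !all(is.na(sco)) || !all(is.na(str))
  base <- paste(areas$seq_region, format(areas$start - 1, scientific = FALSE, trim = TRUE),
                format(areas$end, scientific = FALSE, trim = TRUE), sep = "\t")
  if (has_extra && nrow(areas)) {
    base <- paste(base,
                  ifelse(is.na(lab), ".", lab),
                  ifelse(is.na(sco), "0", format(sco, scientific = FALSE, trim = TRUE)),
                  ifelse(is.na(str), ".", str), sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

FEATURE_TSV_COLUMNS <- c("seq_region", "start", "end", "strand", "score", "label",
                     "weight_score", "p_value")

#' Read/write the tab-separated feature dialect
#'
#' A header-declared TSV with columns drawn from `seq_region`, `start`,
#' `end`, `strand`, `score`, `label`, `weight_score`, `p_value`
#' (coordinates already 1-based inclusive, so reading is an identity
#' mapping).  Rows with a finite `p_value` are motif instances; a file
#' mixing rows with and without `p_value` is rejected naming the first
#' inconsistent row.  This column layout is this package's own dialect.
#'
#' @param path File path.
#' @return A tibble of features with attribute `kind` (`"area"` or
#'   `"motif"`).
#' @export
read_feature_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("seq_region", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation(paste0("TSV header missing mandatory column(s): ",
                            paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(df), FEATURE_TSV_COLUMNS)
  if (length(unknown)) {
    abort_validation(paste0("TSV header has unknown column(s): ",
                            paste(unknown, collapse = ", ")))
  }
  if (nrow(df) && any(!(df$start >= 1 & df$start <= df$end))) {
    bad <- which(!(df$start >= 1 & df$start <= df$end))[1]
    abort_validation(paste0("TSV row ", bad, ": need 1 <= start <= end"))
  }
  kind <- "area"
  if ("p_value" %in% names(df) && nrow(df)) {
    has_p <- !is.na(df$p_value)
    if (all(has_p)) kind <- "motif"
    else if (any(has_p)) {
      abort_validation(paste0("TSV row ", which(has_p != has_p[1])[1],
                              ": mixes motif rows (with p_value) and area rows"))
    }
  }
  df <- tibble::as_tibble(df)
  attr(df, "kind") <- kind
  df
}

#' @rdname read_feature_tsv
#' @param features Tibble of features (areas or motif instances).
#' @return `write_feature_tsv()`: `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  cols <- intersect(FEATURE_TSV_COLUMNS, names(features))
  readr::write_tsv(features[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id`, `name`, `seq_region`, `strand`,
#' `tss` — one row per gene (or per transcript, if per-transcript
#' mapping is wanted).  The `tss` must already be the strand-correct
#' transcription start coordinate.
#'
#' @param path File path.
#' @return A tibble usable as `genes` throughout the package.
#' @export
read_gene_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "name", "seq_region", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_validation(paste0("gene annotation missing column(s): ", paste(miss, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' Read an aligned-FASTA pair as a pairwise alignment
#'
#' The file must contain exactly two gapped records of equal length;
#' the first is the reference.
#'
#' @param path File path.
#' @param ref_offset 1-based genomic position of the first reference
#'   base.
#' @return A [pairwise_alignment()] object.
#' @export
read_alignment_fasta <- function(path, ref_offset = 1) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) != 2L) abort_validation("aligned FASTA must contain exactly two records")
  pairwise_alignment(as.character(x[[1]]), as.character(x[[2]]),
                     ref_name = sub("\\s.*$", "", names(x)[1]),
                     alt_name = sub("\\s.*$", "", names(x)[2]),
                     ref_offset = ref_offset)
}

#' @rdname read_alignment_fasta
#' @param alignment A [pairwise_alignment()] object.
#' @export
write_alignment_fasta <- function(alignment, path) {
  writeLines(c(paste0(">", alignment$ref_name), alignment$ref_aln,
               paste0(">", alignment$alt_name), alignment$alt_aln), path)
  invisible(path)
}

#' Read motif count matrices in JASPAR text format
#'
#' Records look like `>MA0004.1 ARNT` followed by four rows
#' `A  [ 4 19 0 ... ]` (brackets optional), one per letter.
#'
#' @param path File path.
#' @param pseudocount Pseudocount recorded on each returned [pwm()].
#' @return Named list of [pwm()] objects (`library_tag = "jaspar"`).
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (!length(heads)) abort_validation("no JASPAR records found")
  purrr::map(heads, function(h) {
    hdr <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    id <- hdr[1]; nm <- if (length(hdr) > 1) hdr[2] else hdr[1]
    rows <- lines[(h + 1):(h + 4)]
    mat <- purrr::map(rows, function(ln) {
      ln2 <- gsub("[][]", " ", ln)
      f <- strsplit(trimws(ln2), "\\s+")[[1]]
      letter <- f[1]
      vals <- suppressWarnings(as.numeric(f[-1]))
      if (!(letter %in% DNA) || anyNA(vals)) {
        abort_validation(paste0("malformed JASPAR matrix row for ", id, ": ", ln))
      }
      stats::setNames(list(vals), letter)
    })
    mat <- unlist(mat, recursive = FALSE)
    if (!setequal(names(mat), DNA)) {
      abort_validation(paste0("JASPAR record ", id, " lacks rows for all of A,C,G,T"))
    }
    counts <- rbind(A = mat$A, C = mat$C, G = mat$G, T = mat$T)
    pwm(counts, motif_id = id, name = nm, pseudocount = pseudocount,
        library_tag = "jaspar")
  }) |> (\(x) stats::setNames(x, purrr::map_chr(x, "motif_id")))()
}

#' @rdname read_jaspar
#' @param pwms A [pwm()] object or list of them.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- purrr::map(pwms, function(p) {
    c(paste0(">", p$motif_id, " ", p$name),
      purrr::map_chr(DNA, function(b) {
        paste0(b, "  [ ", paste(format(p$counts[, b], trim = TRUE), collapse = " "), " ]")
      }))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read motif count matrices in TRANSFAC text format
#'
#' Blocks delimited by `//`, with `AC`/`ID` accession lines, a
#' `P0 A C G T` header and numbered count rows `01  1 2 3 4  N`.
#'
#' @inheritParams read_jaspar
#' @return Named list of [pwm()] objects (`library_tag = "transfac"`).
#' @export
read_transfac <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(c(TRUE, utils::head(lines, -1) == "//")))
  out <- purrr::compact(purrr::map(blocks, function(bl) {
    po <- grep("^P0|^PO", bl)
    if (!length(po)) return(NULL)
    hdr <- strsplit(trimws(sub("^P0|^PO", "", bl[po[1]])), "\\s+")[[1]]
    if (!setequal(hdr[1:4], DNA)) abort_validation("TRANSFAC P0 header must list A C G T")
    acc <- sub("^AC\\s+", "", grep("^AC\\s", bl, value = TRUE))
    id <- sub("^ID\\s+", "", grep("^ID\\s", bl, value = TRUE))
    motif_id <- if (length(acc)) acc[1] else if (length(id)) id[1] else "transfac_motif"
    nm <- if (length(id)) id[1] else motif_id
    crows <- grep("^[0-9][0-9]\\s", bl, value = TRUE)
    if (!length(crows)) abort_validation(paste0("TRANSFAC record ", motif_id, " has no count rows"))
    counts <- t(vapply(crows, function(ln) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (anyNA(vals)) abort_validation(paste0("malformed TRANSFAC count row: ", ln))
      vals
    }, numeric(4)))
    colnames(counts) <- hdr[1:4]
    counts <- counts[, DNA, drop = FALSE]
    pwm(counts, motif_id = motif_id, name = nm, pseudocount = pseudocount,
        library_tag = "transfac")
  }))
  stats::setNames(out, purrr::map_chr(out, "motif_id"))
}

#' Write motif instances as BED6
#'
#' Score column carries `-log10(p_value)` (capped at 1000); the name
#' column carries `name`.
#'
#' @param instances Tibble with `seq_region`, `start`, `end`, `strand`,
#'   `p_value`.
#' @param path Output path.
#' @param name Feature name to write (e.g. the motif id).
#' @return `path`, invisibly.
#' @export
write_bed6_motifs <- function(instances, path, name = "motif") {
  sc <- pmin(1000, round(-log10(pmax(instances$p_value, 1e-300)), 3))
  writeLines(paste(instances$seq_region,
                   format(instances$start - 1, scientific = FALSE, trim = TRUE),
                   format(instances$end, scientific = FALSE, trim = TRUE),
                   name, sc, instances$strand, sep = "\t"), path)
  invisible(path)
}
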