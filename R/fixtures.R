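# Synthetic fixture generation: a random genome with planted motif
# consensus occurrences, a gene annotation, and random area datasets,
# together with a truth table of everything that was planted or
# constructed.  All randomness is controlled by an explicit seed and
# the generator restores the caller's RNG state.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

#' Random genomic intervals
#'
#' Uniform random intervals for oracle-versus-implementation testing:
#' each interval gets a uniform chromosome, a uniform length in
#' `length_range` and a uniform start such that it fits.
#'
#' @param n Number of intervals.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param length_range Length-2 vector of inclusive length bounds.
#' @param dataset_id Dataset id to stamp on the intervals.
#' @param id_offset First feature id minus one.
#' @return A tibble with `seq_region`, `start`, `end`, `feature_id`,
#'   `dataset_id`.
#' @export
random_areas <- function(n, chrom_lengths = c(chr1 = 100000, chr2 = 100000),
                         length_range = c(1, 500), dataset_id = 1L,
                         id_offset = 0L) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  len <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  maxstart <- chrom_lengths[chrom] - len + 1
  start <- floor(stats::runif(n, 1, maxstart + 1))
  tibble::tibble(
    seq_region = chrom, start = as.double(start), end = as.double(start + len - 1),
    feature_id = as.integer(seq_len(n) + id_offset), dataset_id = as.integer(dataset_id)
  )
}

#' Fixture configuration
#'
#' Defaults describe the standard synthetic test conditions used
#' throughout the package: two 100 kb chromosomes, 200 genes, two area
#' datasets of 1000 uniform intervals of length 1–500, and one 10-mer
#' consensus motif planted 20 times.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_genes Number of genes in the annotation.
#' @param n_datasets Number of area datasets.
#' @param areas_per_dataset Intervals per area dataset.
#' @param area_length_range Inclusive interval-length bounds.
#' @param motif_consensus Named character vector of motif consensus
#'   words (names become motif ids).
#' @param plants_per_motif Number of planted occurrences per motif.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(chrom_lengths = c(chr1 = 100000, chr2 = 100000),
                           n_genes = 200, n_datasets = 2,
                           areas_per_dataset = 1000,
                           area_length_range = c(1, 500),
                           motif_consensus = c(MOTIF1 = "TGACGTCATG"),
                           plants_per_motif = 20) {
  structure(list(
    chrom_lengths = chrom_lengths, n_genes = n_genes, n_datasets = n_datasets,
    areas_per_dataset = areas_per_dataset, area_length_range = area_length_range,
    motif_consensus = motif_consensus, plants_per_motif = plants_per_motif
  ), class = "fixture_config")
}

consensus_pwm <- function(consensus, motif_id, weight = 1) {
  code <- dna_codes(consensus)
  counts <- matrix(0, length(code), 4, dimnames = list(NULL, DNA))
  counts[cbind(seq_along(code), code)] <- weight
  pwm(counts, motif_id = motif_id, name = motif_id, pseudocount = 0,
      library_tag = "user")
}

plant_word <- function(seqs, chrom, pos, word) {
  substr(seqs[[chrom]], pos, pos + nchar(word) - 1) <- word
  seqs
}

#' Generate a synthetic genome fixture with known ground truth
#'
#' Builds, deterministically under `seed`: a uniform-random genome with
#' the configured consensus words planted at non-overlapping forward-
#' strand positions; a gene annotation with random TSSs; the configured
#' random area datasets; consensus-only PWMs for the planted motifs;
#' and truth tables listing every planted motif position and every
#' cross-dataset area overlap (computed directly from the constructed
#' intervals).  With `dir` given, everything is also written to disk
#' (FASTA, TSV, BED, JASPAR).
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed; equal seeds give identical fixtures.
#' @param dir Optional directory to write files into.
#' @return A list: `genome` (named character), `genes`, `areas` (list
#'   of tibbles), `pwms`, `truth_motifs`, `truth_overlaps`, and `paths`
#'   (when `dir` is given).
#' @export
generate_fixture <- function(config = fixture_config(), seed = 1, dir = NULL) {
  cl <- config$chrom_lengths
  for (w in config$motif_consensus) {
    if (nchar(w) > min(cl)) abort_validation("infeasible planting: motif longer than a chromosome")
  }
  with_local_seed(seed, {
    genome <- lapply(cl, random_dna)

    truth_motifs <- tibble::tibble(
      motif_id = character(), seq_region = character(),
      start = double(), end = double(), strand = character()
    )
    occupied <- lapply(cl, function(x) logical(x))
    for (mi in seq_along(config$motif_consensus)) {
      word <- config$motif_consensus[[mi]]
      mid <- names(config$motif_consensus)[mi]
      L <- nchar(word)
      n_plant <- config$plants_per_motif
      planted <- 0L
      guard <- 0L
      while (planted < n_plant) {
        guard <- guard + 1L
        if (guard > 10000L) abort_validation("infeasible planting: could not place all occurrences")
        chrom <- sample(names(cl), 1)
        pos <- sample.int(cl[[chrom]] - L + 1L, 1)
        span <- pos:(pos + L - 1L)
        if (any(occupied[[chrom]][span])) next
        occupied[[chrom]][span] <- TRUE
        genome <- plant_word(genome, chrom, pos, word)
        truth_motifs <- dplyr::bind_rows(truth_motifs, tibble::tibble(
          motif_id = mid, seq_region = chrom, start = pos, end = pos + L - 1,
          strand = "+"
        ))
        planted <- planted + 1L
      }
    }
    truth_motifs <- dplyr::arrange(truth_motifs, .data$motif_id,
                                   .data$seq_region, .data$start)

    genes <- tibble::tibble(
      gene_id = paste0("G", seq_len(config$n_genes)),
      name = paste0("GENE", seq_len(config$n_genes)),
      seq_region = sample(names(cl), config$n_genes, replace = TRUE),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      tss = NA_real_
    )
    genes$tss <- floor(stats::runif(config$n_genes, 1, cl[genes$seq_region] + 1))

    areas <- purrr::map(seq_len(config$n_datasets), function(d) {
      random_areas(config$areas_per_dataset, cl, config$area_length_range,
                   dataset_id = d, id_offset = (d - 1L) * config$areas_per_dataset)
    })

    # cross-dataset overlap truth, straight from the constructed intervals
    truth_overlaps <- tibble::tibble(
      dataset1_id = integer(), id1 = integer(),
      dataset2_id = integer(), id2 = integer()
    )
    if (config$n_datasets >= 2) {
      combos <- utils::combn(config$n_datasets, 2L, simplify = FALSE)
      truth_overlaps <- dplyr::bind_rows(purrr::map(combos, function(cp) {
        a <- areas[[cp[1]]]; b <- areas[[cp[2]]]
        purrr::map_dfr(unique(a$seq_region), function(ch) {
          ac <- a[a$seq_region == ch, ]; bc <- b[b$seq_region == ch, ]
          if (!nrow(ac) || !nrow(bc)) return(NULL)
          ij <- which(outer(ac$start, bc$end, "<=") & outer(ac$end, bc$start, ">="),
                      arr.ind = TRUE)
          tibble::tibble(
            dataset1_id = cp[1], id1 = ac$feature_id[ij[, 1]],
            dataset2_id = cp[2], id2 = bc$feature_id[ij[, 2]]
          )
        })
      }))
    }

    pwms <- purrr::imap(as.list(config$motif_consensus),
                        function(w, nm) consensus_pwm(w, nm))

    out <- list(genome = unlist(genome), genes = genes, areas = areas,
                pwms = pwms, truth_motifs = truth_motifs,
                truth_overlaps = truth_overlaps)

    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        genes = file.path(dir, "genes.tsv"),
        areas = purrr::map_chr(seq_along(areas),
                               ~ file.path(dir, paste0("areas_", .x, ".bed"))),
        pwms = file.path(dir, "motifs.jaspar"),
        truth_motifs = file.path(dir, "truth_motifs.tsv"),
        truth_overlaps = file.path(dir, "truth_overlaps.tsv")
      )
      write_fasta(out$genome, paths$genome)
      readr::write_tsv(genes, paths$genes, progress = FALSE)
      purrr::walk2(areas, paths$areas, write_bed)
      write_jaspar(pwms, paths$pwms)
      readr::write_tsv(truth_motifs, paths$truth_motifs, progress = FALSE)
      readr::write_tsv(truth_overlaps, paths$truth_overlaps, progress = FALSE)
      out$paths <- paths
    }
    out
  })
}
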