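# Area-to-gene assignment via symmetric TSS flanks, and the per-gene
# flank content report.

#' Symmetric flank windows around transcription start sites
#'
#' For each gene returns the window `[max(1, tss - flank_bp),
#' tss + flank_bp]` on the gene's chromosome.  The window is symmetric
#' and strand-independent: for minus-strand genes the `tss` coordinate
#' in the annotation must already be the strand-correct start site.
#'
#' @param genes Gene annotation tibble with columns `gene_id`, `name`,
#'   `seq_region`, `strand`, `tss` (1-based).
#' @param flank_bp Half-width of the window in bp (default 10000, i.e.
#'   a +/-10 kb flank).
#' @return A tibble `gene_id`, `seq_region`, `start`, `end`.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", name = "BDNF", seq_region = "chr1",
#'                     strand = "+", tss = 50000)
#' tss_flank(g)          # [40000, 60000]
#' tss_flank(g, 0)       # degenerate [50000, 50000]
#' @export
tss_flank <- function(genes, flank_bp = 10000) {
  genes <- tibble::as_tibble(genes)
  if (!all(c("gene_id", "seq_region", "tss") %in% names(genes))) {
    abort_validation("genes must have columns gene_id, seq_region, tss")
  }
  if (nrow(genes) && any(genes$tss < 1)) abort_validation("gene tss must be >= 1")
  tibble::tibble(
    gene_id = as.character(genes$gene_id),
    seq_region = as.character(genes$seq_region),
    start = pmax(1, as.double(genes$tss) - flank_bp),
    end = as.double(genes$tss) + flank_bp
  )
}

#' Map areas to genes through TSS flank windows
#'
#' Stores a gene-map row (gene, area) for every area in the given
#' datasets that overlaps the +/-`flank_bp` window around the gene's
#' TSS by at least 1 bp.  Implemented as a sweep-line intersection of
#' the areas against the flank intervals.  Each (dataset, annotation)
#' job is memoised: re-running it adds nothing.
#'
#' @inheritParams can_read
#' @param dataset_ids Area dataset ids to map.
#' @param genes Gene annotation tibble (see [tss_flank()]).
#' @param flank_bp Window half-width in bp.
#' @param annotation_tag Label identifying the gene annotation in the
#'   job registry; supply a new tag to re-map against a different
#'   annotation.
#' @return Number of new gene-map rows stored.
#' @export
map_areas_to_genes <- function(store, user, dataset_ids, genes,
                               flank_bp = 10000, annotation_tag = "default") {
  check_store(store)
  flanks <- tss_flank(genes, flank_bp)
  flank_feats <- tibble::tibble(
    seq_region = flanks$seq_region, start = flanks$start, end = flanks$end,
    feature_id = seq_len(nrow(flanks)), dataset_id = 0L
  )
  n_total <- 0L
  for (ds in dataset_ids) {
    check_kind(store, ds, "area")
    require_read(store, ds, user)
    status <- register_job(store, "gene_map", ds, annotation_tag)
    if (status != "new") next
    recs <- sweep_intersect(areas_of(store, ds), flank_feats)
    if (nrow(recs)) {
      rows <- tibble::tibble(
        gene_id = flanks$gene_id[recs$id2],
        area_id = as.integer(recs$id1),
        area_dataset_id = as.integer(recs$dataset1_id)
      ) |> dplyr::distinct()
      store$area_gene_map <- dplyr::bind_rows(store$area_gene_map, rows)
      n_total <- n_total + nrow(rows)
    }
    log_op(user, "map_areas_to_genes", ds, n_total)
  }
  n_total
}

#' Report the regulatory content of a gene's TSS flank
#'
#' Collects, for one gene, (stage 1) all visible areas of the selected
#' dataset types that overlap the +/-`flank_bp` window around its TSS,
#' and (stage 2) all visible motif instances from the selected motif
#' datasets that overlap at least one stage-1 area.  Motifs in the
#' window that touch no reported area are excluded, so an empty area
#' stage forces an empty motif stage.
#'
#' @inheritParams can_read
#' @param gene_name Gene symbol; must resolve to exactly one gene in
#'   `genes`.
#' @param genes Gene annotation tibble (see [tss_flank()]).
#' @param area_types Character vector of area dataset types/names to
#'   include (`NULL` = all visible area datasets).
#' @param motif_datasets Character vector of motif dataset types/names
#'   to include (`NULL` = all visible motif datasets).
#' @param flank_bp Window half-width in bp.
#' @return A `flank_report` object: list with `gene` (one-row tibble),
#'   `window` (length-2 numeric), `areas` and `motifs` tibbles ordered
#'   by (dataset, start).  Render with [write_flank_report()] or
#'   `autoplot()`.
#' @export
flank_report <- function(store, user, gene_name, genes, area_types = NULL,
                         motif_datasets = NULL, flank_bp = 10000) {
  check_store(store)
  genes <- tibble::as_tibble(genes)
  hit <- genes[genes$name == gene_name, ]
  if (nrow(hit) == 0L) abort_not_found(paste0("gene not found: ", gene_name))
  if (nrow(hit) > 1L) {
    abort_ambiguous(paste0("gene name '", gene_name, "' is ambiguous: ",
                           paste(hit$gene_id, collapse = ", ")))
  }
  win <- tss_flank(hit, flank_bp)
  v <- visible_datasets(store, user)
  sel_area <- if (is.null(area_types)) {
    v$dataset_id[v$content_kind == "area"]
  } else {
    v$dataset_id[v$content_kind == "area" &
                   (v$ds_type %in% area_types | v$name %in% area_types)]
  }
  sel_motif <- if (is.null(motif_datasets)) {
    v$dataset_id[v$content_kind == "motif"]
  } else {
    v$dataset_id[v$content_kind == "motif" &
                   (v$ds_type %in% motif_datasets | v$name %in% motif_datasets)]
  }
  areas <- store$area |>
    dplyr::filter(.data$dataset_id %in% sel_area,
                  .data$seq_region == win$seq_region,
                  .data$start <= win$end, .data$end >= win$start) |>
    dplyr::arrange(.data$dataset_id, .data$start)
  motifs <- store$motif |>
    dplyr::filter(.data$dataset_id %in% sel_motif,
                  .data$seq_region == win$seq_region,
                  .data$start <= win$end, .data$end >= win$start)
  if (nrow(motifs) && nrow(areas)) {
    keep <- sweep_intersect(areas, motifs)
    motifs <- motifs[motifs$motif_id %in% keep$id2, ] |>
      dplyr::arrange(.data$dataset_id, .data$start)
  } else {
    motifs <- motifs[0, ]
  }
  structure(
    list(gene = hit, window = c(win$start, win$end), areas = areas, motifs = motifs),
    class = "flank_report"
  )
}

#' @export
print.flank_report <- function(x, ...) {
  cat("<flank_report> gene ", x$gene$name, " (", x$gene$gene_id, ") ",
      x$gene$seq_region, ":", x$window[1], "-", x$window[2], "\n",
      "  areas: ", nrow(x$areas), "   motifs intersecting areas: ",
      nrow(x$motifs), "\n", sep = "")
  invisible(x)
}

#' Write a flank report as tab-separated text
#'
#' One block per section (`area`, `motif`), each row tagged with its
#' dataset id; the canonical machine-readable rendering of
#' [flank_report()].
#'
#' @param report A `flank_report` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flank_report <- function(report, path) {
  a <- report$areas |>
    dplyr::transmute(section = "area", id = .data$area_id, .data$dataset_id,
                     .data$seq_region, .data$start, .data$end, .data$strand,
                     score = .data$score)
  m <- report$motifs |>
    dplyr::transmute(section = "motif", id = .data$motif_id, .data$dataset_id,
                     .data$seq_region, .data$start, .data$end, .data$strand,
                     score = .data$weight_score)
  readr::write_tsv(dplyr::bind_rows(a, m), path)
  invisible(path)
}

#' Tidy a flank report into one feature table
#'
#' @param x A `flank_report` object.
#' @param ... Unused.
#' @return A tibble with one row per reported feature.
#' @exportS3Method generics::tidy
tidy.flank_report <- function(x, ...) {
  dplyr::bind_rows(
    x$areas |> dplyr::transmute(kind = "area", id = .data$area_id,
                                .data$dataset_id, .data$seq_region,
                                .data$start, .data$end, .data$strand),
    x$motifs |> dplyr::transmute(kind = "motif", id = .data$motif_id,
                                 .data$dataset_id, .data$seq_region,
                                 .data$start, .data$end, .data$strand)
  )
}

#' Track plot of a flank report
#'
#' One lane per dataset, rectangles at feature spans, the TSS marked by
#' a vertical line.  A quick content overview, not a genome-browser
#' rendering.
#'
#' @param object A `flank_report` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.flank_report <- function(object, ...) {
  df <- tidy.flank_report(object)
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle(paste0("No features in flank of ", object$gene$name)))
  }
  df$lane <- paste0(df$kind, " ds", df$dataset_id)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = as.integer(factor(.data$lane)) - 0.4,
      ymax = as.integer(factor(.data$lane)) + 0.4,
      fill = .data$kind)) +
    ggplot2::geom_vline(xintercept = object$gene$tss, linetype = 2) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(df$lane))),
      labels = levels(factor(df$lane))) +
    ggplot2::labs(x = paste0(object$gene$seq_region, " position"), y = NULL,
                  title = paste0("TSS flank of ", object$gene$name)) +
    ggplot2::theme_minimal()
}
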