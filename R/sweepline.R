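# Sweep-line interval intersection and the dataset-level intersection
# procedures built on it.
#
# The core algorithm: all intervals go into a working list W sorted by
# left end; a sweep set S holds the intervals whose span reaches the
# current position.  For each interval K taken from W in order, every
# interval still in S after expiring the ones that end before K starts
# overlaps K, so the pairs (S x {K}) are exactly the new overlaps.  This
# reports all k overlapping pairs among n intervals in O(n log n + k).

sweep_prepare <- function(features, tag, what) {
  f <- tibble::as_tibble(features)
  if (!"feature_id" %in% names(f)) {
    if ("area_id" %in% names(f)) f$feature_id <- f$area_id
    else if ("motif_id" %in% names(f)) f$feature_id <- f$motif_id
    else abort_validation(paste0(what, " must carry a feature_id (or area_id/motif_id) column"))
  }
  need <- c("seq_region", "start", "end", "feature_id", "dataset_id")
  miss <- setdiff(need, names(f))
  if (length(miss)) abort_validation(paste0(what, " missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(f) && any(is.na(f$seq_region) | !nzchar(as.character(f$seq_region)))) {
    abort_validation(paste0(what, ": interval with unknown/empty seq_region"))
  }
  tibble::tibble(
    seq_region = as.character(f$seq_region), start = as.double(f$start),
    end = as.double(f$end), feature_id = f$feature_id,
    dataset_id = f$dataset_id, tag = tag
  )
}

#' Report all overlapping interval pairs between two feature sets
#'
#' Emits exactly the cross-set pairs on the same `seq_region` that share
#' at least one base in 1-based inclusive coordinates (adjacent
#' intervals do not overlap), each unordered pair once, with the shared
#' span `[max(starts), min(ends)]`.  Strand is ignored.  With
#' `features_b = NULL` the single set is intersected against itself and
#' self-pairs (x, x) are suppressed.  Inputs need not be sorted; output
#' order is deterministic (seq_region, then sweep order).
#'
#' @param features_a,features_b Tibbles with columns `seq_region`,
#'   `start`, `end`, `feature_id` (or `area_id`/`motif_id`) and
#'   `dataset_id`.
#' @return A tibble with columns `id1`, `dataset1_id`, `id2`,
#'   `dataset2_id`, `seq_region`, `overlap_start`, `overlap_end`, where
#'   side 1 comes from `features_a` (for a self-intersection, the pair
#'   is ordered by feature id).
#' @examples
#' a <- tibble::tibble(seq_region = "chr1", start = 100, end = 200,
#'                     feature_id = 1L, dataset_id = 1L)
#' b <- tibble::tibble(seq_region = "chr1", start = 150, end = 250,
#'                     feature_id = 2L, dataset_id = 2L)
#' sweep_intersect(a, b)  # one pair, overlap [150, 200]
#' @export
sweep_intersect <- function(features_a, features_b = NULL) {
  self_mode <- is.null(features_b)
  w <- sweep_prepare(features_a, "a", "features_a")
  if (!self_mode) {
    w <- dplyr::bind_rows(w, sweep_prepare(features_b, "b", "features_b"))
  }
  out <- list()
  for (chrom in sort(unique(w$seq_region))) {
    wc <- w[w$seq_region == chrom, ]
    ord <- order(wc$start, wc$end, wc$feature_id)
    wc <- wc[ord, ]
    n <- nrow(wc)
    act <- integer(0)                       # indices into wc currently in S
    res_i <- vector("list", n); res_j <- vector("list", n)
    for (k in seq_len(n)) {
      if (length(act)) act <- act[wc$end[act] >= wc$start[k]]
      partners <- if (self_mode) act else act[wc$tag[act] != wc$tag[k]]
      if (length(partners)) {
        res_i[[k]] <- partners
        res_j[[k]] <- rep.int(k, length(partners))
      }
      act <- c(act, k)
    }
    i <- unlist(res_i); j <- unlist(res_j)
    if (!length(i)) next
    # orient: side 1 = features_a (or smaller feature id in self mode)
    if (self_mode) {
      flip <- wc$feature_id[i] > wc$feature_id[j]
    } else {
      flip <- wc$tag[i] == "b"
    }
    s1 <- ifelse(flip, j, i); s2 <- ifelse(flip, i, j)
    out[[chrom]] <- tibble::tibble(
      id1 = wc$feature_id[s1], dataset1_id = wc$dataset_id[s1],
      id2 = wc$feature_id[s2], dataset2_id = wc$dataset_id[s2],
      seq_region = chrom,
      overlap_start = pmax(wc$start[i], wc$start[j]),
      overlap_end = pmin(wc$end[i], wc$end[j])
    )
  }
  if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    id1 = integer(), dataset1_id = integer(), id2 = integer(),
    dataset2_id = integer(), seq_region = character(),
    overlap_start = double(), overlap_end = double()
  )
}

areas_of <- function(store, dataset_id) {
  store$area[store$area$dataset_id == dataset_id, ]
}

check_kind <- function(store, dataset_id, kind) {
  row <- dataset_row(store, dataset_id)
  if (row$content_kind != kind) {
    hint <- if (kind == "area") "use the area-motif intersection variant" else "this variant needs a motif dataset"
    abort_kind(paste0("dataset ", dataset_id, " has content_kind '",
                      row$content_kind, "', expected '", kind, "'; ", hint))
  }
  invisible(TRUE)
}

#' Compute and store area–area intersections for dataset pairs
#'
#' For each pair not already recorded in the job registry, runs
#' [sweep_intersect()] on the two datasets' areas and stores the result
#' in the `area_intersection` table with the smaller dataset id first.
#' Re-running a pair (in either orientation) is a recorded no-op.
#'
#' @inheritParams can_read
#' @param pairs A two-column data frame or a list of length-2 vectors of
#'   dataset ids.
#' @return A tibble with one row per requested pair: `dataset1_id`,
#'   `dataset2_id`, `status` (`"new"`/`"already_done"`), `n_new`.
#' @export
intersect_dataset_pairs <- function(store, user, pairs) {
  check_store(store)
  if (is.data.frame(pairs)) {
    pairs <- purrr::map2(pairs[[1]], pairs[[2]], c)
  }
  res <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    p <- pairs[[pi]]
    d1 <- p[[1]]; d2 <- p[[2]]
    check_kind(store, d1, "area"); check_kind(store, d2, "area")
    require_read(store, d1, user); require_read(store, d2, user)
    status <- register_job(store, "area_area", d1, d2)
    n_new <- 0L
    if (status == "new") {
      recs <- if (d1 == d2) sweep_intersect(areas_of(store, d1)) else
        sweep_intersect(areas_of(store, d1), areas_of(store, d2))
      if (nrow(recs)) {
        flip <- recs$dataset1_id > recs$dataset2_id
        recs <- tibble::tibble(
          area1_id = as.integer(ifelse(flip, recs$id2, recs$id1)),
          dataset1_id = as.integer(ifelse(flip, recs$dataset2_id, recs$dataset1_id)),
          area2_id = as.integer(ifelse(flip, recs$id1, recs$id2)),
          dataset2_id = as.integer(ifelse(flip, recs$dataset1_id, recs$dataset2_id)),
          seq_region = recs$seq_region,
          overlap_start = recs$overlap_start, overlap_end = recs$overlap_end
        )
        store$area_intersection <- dplyr::bind_rows(store$area_intersection, recs)
        n_new <- nrow(recs)
      }
      log_op(user, "intersect_area_area", c(d1, d2), n_new)
    }
    res[[pi]] <- tibble::tibble(dataset1_id = d1, dataset2_id = d2,
                                status = status, n_new = n_new)
  }
  if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    dataset1_id = integer(), dataset2_id = integer(),
    status = character(), n_new = integer())
}

visible_area_datasets <- function(store, user) {
  v <- visible_datasets(store, user)
  v$dataset_id[v$content_kind == "area"]
}

#' Intersect all visible area-dataset pairs, or one dataset against all
#'
#' `intersect_all_pairs()` runs every unordered pair of area datasets
#' visible to the user; `intersect_one_vs_all()` runs one dataset
#' against every other visible area dataset.  Pairs already in the job
#' registry are skipped.
#'
#' @inheritParams can_read
#' @return As [intersect_dataset_pairs()].
#' @export
intersect_all_pairs <- function(store, user) {
  ds <- visible_area_datasets(store, user)
  if (length(ds) < 2L) return(intersect_dataset_pairs(store, user, list()))
  idx <- utils::combn(sort(ds), 2L, simplify = FALSE)
  intersect_dataset_pairs(store, user, idx)
}

#' @rdname intersect_all_pairs
#' @export
intersect_one_vs_all <- function(store, user, dataset_id) {
  check_kind(store, dataset_id, "area")
  require_read(store, dataset_id, user)
  others <- setdiff(visible_area_datasets(store, user), dataset_id)
  intersect_dataset_pairs(store, user, purrr::map(others, ~ c(dataset_id, .x)))
}

#' Compute and store area–motif intersections
#'
#' Intersects areas with motif instances: one area dataset against one
#' motif dataset, one area dataset against all visible motif datasets
#' (`motif_dataset_id = NULL`), or one motif dataset against all visible
#' area datasets (`area_dataset_id = NULL`).  Results are stored in the
#' `motif_intersection` table keyed (area_id, area_dataset_id, motif_id,
#' motif_dataset_id); completed pairs are skipped via the job registry.
#'
#' @inheritParams can_read
#' @param area_dataset_id,motif_dataset_id Dataset ids; leave exactly
#'   one `NULL` for the one-vs-all variants.
#' @return A tibble with one row per (area, motif) dataset pair run:
#'   `area_dataset_id`, `motif_dataset_id`, `status`, `n_new`.
#' @export
intersect_area_motif <- function(store, user, area_dataset_id = NULL,
                                 motif_dataset_id = NULL) {
  check_store(store)
  if (is.null(area_dataset_id) && is.null(motif_dataset_id)) {
    abort_validation("give at least one of area_dataset_id, motif_dataset_id")
  }
  v <- visible_datasets(store, user)
  area_ids <- if (is.null(area_dataset_id)) v$dataset_id[v$content_kind == "area"] else area_dataset_id
  motif_ids <- if (is.null(motif_dataset_id)) v$dataset_id[v$content_kind == "motif"] else motif_dataset_id
  res <- list()
  for (ad in area_ids) {
    check_kind(store, ad, "area"); require_read(store, ad, user)
    for (md in motif_ids) {
      check_kind(store, md, "motif"); require_read(store, md, user)
      status <- register_job(store, "area_motif", ad, md)
      n_new <- 0L
      if (status == "new") {
        motifs <- store$motif[store$motif$dataset_id == md, ]
        recs <- sweep_intersect(areas_of(store, ad), motifs)
        if (nrow(recs)) {
          recs <- tibble::tibble(
            area_id = as.integer(recs$id1), area_dataset_id = as.integer(recs$dataset1_id),
            motif_id = as.integer(recs$id2), motif_dataset_id = as.integer(recs$dataset2_id),
            seq_region = recs$seq_region,
            overlap_start = recs$overlap_start, overlap_end = recs$overlap_end
          )
          store$motif_intersection <- dplyr::bind_rows(store$motif_intersection, recs)
          n_new <- nrow(recs)
        }
        log_op(user, "intersect_area_motif", c(ad, md), n_new)
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        area_dataset_id = ad, motif_dataset_id = md, status = status, n_new = n_new
      )
    }
  }
  if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    area_dataset_id = integer(), motif_dataset_id = integer(),
    status = character(), n_new = integer()
  )
}
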