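#' Create an empty feature store
#'
#' A store is a small in-memory relational database holding regulatory
#' feature datasets and every result computed on them.  It mirrors the
#' table layout used by dataset-centric regulatory-genomics databases:
#' `dataset` and `dataset_attr` describe each collection, `area` and
#' `motif` hold the genomic features, `area_intersection`,
#' `motif_intersection` and `area_gene_map` hold computed results, and
#' `access_grant` plus `job_registry` carry the per-user access-control
#' and job-memoisation state.  Each table is an ordinary tibble; the
#' whole store round-trips through a single JSON file (see
#' [write_store()]).
#'
#' The store is an environment, so dataset-level operations mutate it in
#' place and return their result (an id, a count, a report) for piping.
#' All mutating operations take an explicit `user` argument; there is no
#' ambient identity.  The reserved user name `"public"` is the anonymous
#' user: it can never hold grants and sees only public datasets.
#'
#' @return An object of class `regstore`.
#' @examples
#' store <- regstore()
#' d1 <- create_dataset(store, "u1", "test area", "test class", "test area")
#' add_areas(store, "u1", d1,
#'   tibble::tibble(seq_region = "chr1", start = 100, end = 200))
#' @export
regstore <- function() {
  store <- new.env(parent = emptyenv())
  store$dataset <- tibble::tibble(
    dataset_id = integer(), name = character(), ds_class = character(),
    ds_type = character(), species = character(), content_kind = character(),
    is_public = logical()
  )
  store$dataset_attr <- tibble::tibble(
    dataset_id = integer(), name = character(), value = character()
  )
  store$area <- tibble::tibble(
    area_id = integer(), dataset_id = integer(), seq_region = character(),
    start = double(), end = double(), strand = character(),
    score = double(), label = character()
  )
  store$motif <- tibble::tibble(
    motif_id = integer(), dataset_id = integer(), seq_region = character(),
    start = double(), end = double(), strand = character(),
    weight_score = double(), p_value = double()
  )
  store$area_intersection <- tibble::tibble(
    area1_id = integer(), dataset1_id = integer(),
    area2_id = integer(), dataset2_id = integer(),
    seq_region = character(), overlap_start = double(), overlap_end = double()
  )
  store$motif_intersection <- tibble::tibble(
    area_id = integer(), area_dataset_id = integer(),
    motif_id = integer(), motif_dataset_id = integer(),
    seq_region = character(), overlap_start = double(), overlap_end = double()
  )
  store$area_gene_map <- tibble::tibble(
    gene_id = character(), area_id = integer(), area_dataset_id = integer()
  )
  store$access_grant <- tibble::tibble(
    dataset_id = integer(), user = character(), level = character()
  )
  store$job_registry <- tibble::tibble(
    procedure = character(), key1 = character(), key2 = character()
  )
  store$next_dataset_id <- 1L
  store$next_area_id <- 1L
  store$next_motif_id <- 1L
  class(store) <- "regstore"
  store
}

#' @export
print.regstore <- function(x, ...) {
  cat("<regstore>\n")
  cat("  datasets:           ", nrow(x$dataset),
      " (", sum(x$dataset$is_public), " public)\n", sep = "")
  cat("  areas:              ", nrow(x$area), "\n", sep = "")
  cat("  motif instances:    ", nrow(x$motif), "\n", sep = "")
  cat("  area intersections: ", nrow(x$area_intersection), "\n", sep = "")
  cat("  motif intersections:", nrow(x$motif_intersection), "\n")
  cat("  gene-map rows:      ", nrow(x$area_gene_map), "\n", sep = "")
  invisible(x)
}

STORE_TABLES <- c(
  "dataset", "dataset_attr", "area", "motif", "area_intersection",
  "motif_intersection", "area_gene_map", "access_grant", "job_registry"
)

ANONYMOUS_USER <- "public"

check_store <- function(store) {
  if (!inherits(store, "regstore")) {
    abort_validation("`store` must be a regstore object")
  }
  invisible(store)
}

#' Serialize a store to its canonical JSON form
#'
#' Used both for persistence and for byte-level idempotency checks: two
#' stores with identical content serialize to identical strings.
#'
#' @param store A [regstore()] object.
#' @return A JSON string.
#' @export
store_json <- function(store) {
  check_store(store)
  payload <- c(
    lapply(stats::setNames(STORE_TABLES, STORE_TABLES), function(tb) store[[tb]]),
    list(counters = list(
      next_dataset_id = store$next_dataset_id,
      next_area_id = store$next_area_id,
      next_motif_id = store$next_motif_id
    ))
  )
  jsonlite::toJSON(payload, dataframe = "columns", digits = NA, na = "null",
                   auto_unbox = TRUE)
}

#' Persist a store to a single JSON file
#'
#' @param store A [regstore()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  writeLines(store_json(store), path)
  invisible(path)
}

#' Load a store from a JSON file written by [write_store()]
#'
#' @param path File path to read.
#' @return A [regstore()] object.
#' @export
read_store <- function(path) {
  if (!file.exists(path)) abort_not_found(paste0("store file not found: ", path))
  raw <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  store <- regstore()
  for (tb in STORE_TABLES) {
    proto <- store[[tb]]
    cols <- raw[[tb]]
    if (is.null(cols) || length(cols) == 0L) next
    df <- tibble::as_tibble(lapply(stats::setNames(names(proto), names(proto)), function(cn) {
      v <- cols[[cn]]
      if (is.null(v)) v <- vector(mode = class(proto[[cn]])[1], length = 0L)
      mode_target <- proto[[cn]]
      if (is.integer(mode_target)) as.integer(v)
      else if (is.double(mode_target)) as.double(v)
      else if (is.logical(mode_target)) as.logical(v)
      else as.character(v)
    }))
    store[[tb]] <- df
  }
  store$next_dataset_id <- as.integer(raw$counters$next_dataset_id)
  store$next_area_id <- as.integer(raw$counters$next_area_id)
  store$next_motif_id <- as.integer(raw$counters$next_motif_id)
  store
}

# Structured log line for every mutating operation; disabled unless the
# option "regstore.log" names a writable file (the store itself stays
# timestamp-free so identical content is byte-identical on disk).
log_op <- function(user, op, dataset_ids = integer(), n = NA_integer_) {
  path <- getOption("regstore.log", NULL)
  if (is.null(path)) return(invisible(NULL))
  line <- paste(
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), user, op,
    paste(dataset_ids, collapse = ","), n,
    sep = "\t"
  )
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}

#' Audit a store's referential integrity
#'
#' Checks that no stored record references a missing dataset or feature,
#' that grant and publicity invariants hold, and that every intersection
#' span is contained in both of its features.  Returns a tibble of
#' violations; an empty tibble means the store is consistent.
#'
#' @param store A [regstore()] object.
#' @return A tibble with columns `check` and `detail` (zero rows when clean).
#' @export
audit_store <- function(store) {
  check_store(store)
  bad <- list()
  note <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }
  ds_ids <- store$dataset$dataset_id
  if (anyDuplicated(ds_ids)) note("dataset_id_unique", "duplicate dataset_id")

  ref_ds <- function(ids, where) {
    miss <- setdiff(unique(ids), ds_ids)
    if (length(miss)) note("dataset_ref", paste0(where, ": missing dataset ", paste(miss, collapse = ",")))
  }
  ref_ds(store$dataset_attr$dataset_id, "dataset_attr")
  ref_ds(store$area$dataset_id, "area")
  ref_ds(store$motif$dataset_id, "motif")
  ref_ds(store$access_grant$dataset_id, "access_grant")
  ref_ds(c(store$area_intersection$dataset1_id, store$area_intersection$dataset2_id), "area_intersection")
  ref_ds(c(store$motif_intersection$area_dataset_id, store$motif_intersection$motif_dataset_id), "motif_intersection")
  ref_ds(store$area_gene_map$area_dataset_id, "area_gene_map")

  if (length(setdiff(unique(c(store$area_intersection$area1_id, store$area_intersection$area2_id,
                              store$motif_intersection$area_id, store$area_gene_map$area_id)),
                     store$area$area_id))) {
    note("area_ref", "intersection or gene-map row references a missing area")
  }
  if (length(setdiff(unique(store$motif_intersection$motif_id), store$motif$motif_id))) {
    note("motif_ref", "motif_intersection references a missing motif instance")
  }

  # job registry keys must reference live datasets (numeric keys only)
  jr <- store$job_registry
  num_keys <- suppressWarnings(as.integer(c(jr$key1, jr$key2)))
  miss <- setdiff(unique(num_keys[!is.na(num_keys)]), ds_ids)
  if (length(miss)) note("job_ref", paste0("job_registry references missing dataset ", paste(miss, collapse = ",")))

  # every non-public dataset must keep >= 1 owner; grants unique per (ds, user)
  g <- store$access_grant
  if (nrow(g) && anyDuplicated(g[, c("dataset_id", "user")])) {
    note("grant_unique", "multiple grants for one (dataset, user)")
  }
  owners <- table(factor(g$dataset_id[g$level == "owner"], levels = ds_ids))
  orphan <- ds_ids[owners == 0]
  if (length(orphan)) note("owner_present", paste0("dataset without owner: ", paste(orphan, collapse = ",")))
  if (any(g$user == ANONYMOUS_USER)) note("anonymous_grant", "grant held by the anonymous user")

  # intersection spans contained in both features
  ai <- store$area_intersection
  if (nrow(ai)) {
    a <- store$area
    s1 <- match(ai$area1_id, a$area_id); s2 <- match(ai$area2_id, a$area_id)
    ok <- ai$overlap_start <= ai$overlap_end &
      ai$overlap_start >= pmax(a$start[s1], a$start[s2]) &
      ai$overlap_end <= pmin(a$end[s1], a$end[s2])
    if (!all(ok)) note("overlap_span", "area_intersection span outside features")
  }
  if (length(bad)) dplyr::bind_rows(bad) else tibble::tibble(check = character(), detail = character())
}
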