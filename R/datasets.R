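# Dataset lifecycle, access control and the job-memoisation registry.
#
# Access model: two levels per (dataset, user) — "owner" (full control,
# manages grants) and "reader" (sees the data, cannot modify anything).
# Making a dataset public is irrevocable and a public dataset cannot be
# deleted; results computed on datasets inherit visibility from the
# datasets they reference (conjunction over all referenced datasets).

dataset_row <- function(store, dataset_id) {
  i <- match(dataset_id, store$dataset$dataset_id)
  if (is.na(i)) abort_not_found(paste0("dataset not found: ", dataset_id))
  store$dataset[i, ]
}

grant_level <- function(store, dataset_id, user) {
  g <- store$access_grant
  lv <- g$level[g$dataset_id == dataset_id & g$user == user]
  if (length(lv)) lv[1] else NA_character_
}

is_owner <- function(store, dataset_id, user) {
  identical(grant_level(store, dataset_id, user), "owner")
}

#' Can a user read a dataset?
#'
#' True when the dataset is public or the user holds any grant on it.
#'
#' @param store A [regstore()] object.
#' @param user User name; `"public"` is the anonymous user.
#' @param dataset_id Dataset id.
#' @return Logical scalar.
#' @export
can_read <- function(store, user, dataset_id) {
  row <- dataset_row(store, dataset_id)
  row$is_public || !is.na(grant_level(store, dataset_id, user))
}

require_owner <- function(store, dataset_id, user, what) {
  dataset_row(store, dataset_id)
  if (!is_owner(store, dataset_id, user)) {
    abort_permission(paste0("user '", user, "' is not an owner of dataset ",
                            dataset_id, "; cannot ", what))
  }
  invisible(TRUE)
}

require_read <- function(store, dataset_id, user) {
  if (!can_read(store, user, dataset_id)) {
    abort_permission(paste0("user '", user, "' cannot read dataset ", dataset_id))
  }
  invisible(TRUE)
}

#' Register a new dataset
#'
#' Creates an empty dataset owned by `user`.  Datasets are described by a
#' free-text class and type (e.g. class `"Histone"`, type `"H3K4me3"`)
#' plus optional name:value attributes such as the cell type of origin.
#'
#' @param store A [regstore()] object.
#' @param user Creating user; becomes the first owner.  The anonymous
#'   user `"public"` cannot create datasets.
#' @param name Dataset name (non-empty; names need not be unique — ids
#'   are the keys).
#' @param ds_class,ds_type Free-text class/type labels.
#' @param species Free-text species tag.
#' @param content_kind `"area"` or `"motif"`.
#' @param attributes Named character vector or list of attribute
#'   name:value pairs.
#' @return The new integer `dataset_id`.
#' @export
create_dataset <- function(store, user, name, ds_class = "", ds_type = "",
                           species = "", content_kind = c("area", "motif"),
                           attributes = NULL) {
  check_store(store)
  content_kind <- match.arg(content_kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("dataset `name` must be a non-empty string")
  }
  if (identical(user, ANONYMOUS_USER)) {
    abort_permission("the anonymous user cannot create datasets")
  }
  id <- store$next_dataset_id
  store$next_dataset_id <- id + 1L
  store$dataset <- dplyr::bind_rows(store$dataset, tibble::tibble(
    dataset_id = id, name = name, ds_class = ds_class, ds_type = ds_type,
    species = species, content_kind = content_kind, is_public = FALSE
  ))
  store$access_grant <- dplyr::bind_rows(store$access_grant, tibble::tibble(
    dataset_id = id, user = user, level = "owner"
  ))
  if (length(attributes)) {
    attributes <- unlist(attributes)
    store$dataset_attr <- dplyr::bind_rows(store$dataset_attr, tibble::tibble(
      dataset_id = id, name = names(attributes), value = unname(as.character(attributes))
    ))
  }
  log_op(user, "create_dataset", id, 1L)
  id
}

#' Retrieve a dataset's attributes
#'
#' @inheritParams can_read
#' @return A tibble with columns `name`, `value`.
#' @export
get_attributes <- function(store, user, dataset_id) {
  require_read(store, dataset_id, user)
  store$dataset_attr |>
    dplyr::filter(.data$dataset_id == .env$dataset_id) |>
    dplyr::select("name", "value")
}

#' Delete a dataset and everything that depends on it
#'
#' Removal cascades: the dataset's features, every stored intersection
#' referencing it, every gene-map row for its areas, its job-registry
#' entries, grants and attributes all go.  Only an owner may delete, and
#' a public dataset can never be deleted.
#'
#' @inheritParams can_read
#' @return Count of cascaded data records removed (features,
#'   intersections and gene-map rows; bookkeeping rows are removed but
#'   not counted).
#' @export
delete_dataset <- function(store, user, dataset_id) {
  check_store(store)
  row <- dataset_row(store, dataset_id)
  require_owner(store, dataset_id, user, "delete it")
  if (row$is_public) {
    abort_permission(paste0("dataset ", dataset_id, " is public and cannot be deleted"))
  }
  id <- dataset_id
  n_feat <- sum(store$area$dataset_id == id) + sum(store$motif$dataset_id == id)
  doomed_areas <- store$area$area_id[store$area$dataset_id == id]

  ai_hit <- store$area_intersection$dataset1_id == id |
    store$area_intersection$dataset2_id == id
  mi_hit <- store$motif_intersection$area_dataset_id == id |
    store$motif_intersection$motif_dataset_id == id
  gm_hit <- store$area_gene_map$area_dataset_id == id
  n_cascade <- n_feat + sum(ai_hit) + sum(mi_hit) + sum(gm_hit)

  store$area_intersection <- store$area_intersection[!ai_hit, ]
  store$motif_intersection <- store$motif_intersection[!mi_hit, ]
  store$area_gene_map <- store$area_gene_map[!gm_hit, ]
  store$area <- store$area[store$area$dataset_id != id, ]
  store$motif <- store$motif[store$motif$dataset_id != id, ]
  store$dataset_attr <- store$dataset_attr[store$dataset_attr$dataset_id != id, ]
  store$access_grant <- store$access_grant[store$access_grant$dataset_id != id, ]
  key <- as.character(id)
  store$job_registry <- store$job_registry[
    store$job_registry$key1 != key & store$job_registry$key2 != key, ]
  store$dataset <- store$dataset[store$dataset$dataset_id != id, ]
  log_op(user, "delete_dataset", id, n_cascade)
  n_cascade
}

#' Make a dataset public (irrevocable)
#'
#' After publication every user, including the anonymous `"public"`
#' user, can read the dataset, and stored results referencing only
#' public datasets become visible to everyone.  There is deliberately no
#' inverse operation: a public dataset stays public and can no longer be
#' deleted.
#'
#' @inheritParams can_read
#' @return `TRUE`, invisibly.  Publishing an already-public dataset is
#'   an idempotent no-op.
#' @export
make_public <- function(store, user, dataset_id) {
  check_store(store)
  require_owner(store, dataset_id, user, "publish it")
  i <- match(dataset_id, store$dataset$dataset_id)
  store$dataset$is_public[i] <- TRUE
  log_op(user, "make_public", dataset_id)
  invisible(TRUE)
}

#' Grant or revoke access to a dataset
#'
#' Only owners manage grants.  A user holds at most one grant per
#' dataset (re-granting changes the level).  Revoking the sole owner is
#' refused so every dataset always has at least one owner.
#'
#' @inheritParams can_read
#' @param actor The user performing the grant/revoke (must be an owner).
#' @param level `"owner"` or `"reader"`.
#' @return `TRUE`, invisibly.
#' @export
grant_access <- function(store, actor, dataset_id, user, level = c("reader", "owner")) {
  check_store(store)
  level <- match.arg(level)
  require_owner(store, dataset_id, actor, "manage access")
  if (identical(user, ANONYMOUS_USER)) {
    abort_validation("cannot grant to the anonymous user; use make_public()")
  }
  g <- store$access_grant
  hit <- g$dataset_id == dataset_id & g$user == user
  if (any(hit)) {
    # a downgrade is a revoke-and-regrant: the sole owner stays protected
    if (g$level[hit][1] == "owner" && level == "reader" &&
        sum(g$dataset_id == dataset_id & g$level == "owner") <= 1L) {
      abort_integrity(paste0("cannot downgrade the sole owner of dataset ", dataset_id))
    }
    store$access_grant$level[hit] <- level
  } else {
    store$access_grant <- dplyr::bind_rows(g, tibble::tibble(
      dataset_id = dataset_id, user = user, level = level
    ))
  }
  log_op(actor, "grant_access", dataset_id)
  invisible(TRUE)
}

#' @rdname grant_access
#' @export
revoke_access <- function(store, actor, dataset_id, user) {
  check_store(store)
  require_owner(store, dataset_id, actor, "manage access")
  g <- store$access_grant
  hit <- g$dataset_id == dataset_id & g$user == user
  if (!any(hit)) abort_not_found(paste0("no grant for user '", user, "' on dataset ", dataset_id))
  if (g$level[hit][1] == "owner") {
    n_owner <- sum(g$dataset_id == dataset_id & g$level == "owner")
    if (n_owner <= 1L) {
      abort_integrity(paste0("cannot revoke the sole owner of dataset ", dataset_id))
    }
  }
  store$access_grant <- g[!hit, ]
  log_op(actor, "revoke_access", dataset_id)
  invisible(TRUE)
}

validate_intervals <- function(df, what) {
  if (!all(c("seq_region", "start", "end") %in% names(df))) {
    abort_validation(paste0(what, " must have columns seq_region, start, end"))
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$seq_region) | !nzchar(df$seq_region))) {
    abort_validation(paste0(what, ": empty seq_region in row ",
                            which(is.na(df$seq_region) | !nzchar(df$seq_region))[1]))
  }
  bad <- which(!(df$start >= 1 & df$start <= df$end))
  if (length(bad)) {
    abort_validation(paste0(
      what, ": invalid coordinates in row ", bad[1], " (start=",
      df$start[bad[1]], ", end=", df$end[bad[1]],
      "); need 1 <= start <= end — no records inserted"))
  }
  invisible(df)
}

#' Add areas or motif instances to a dataset
#'
#' Insertion is all-or-nothing: one invalid record fails the whole
#' batch.  Fresh feature ids are assigned in input order, but no
#' downstream result depends on insertion order.
#'
#' @inheritParams can_read
#' @param areas Tibble with columns `seq_region`, `start`, `end` and
#'   optionally `strand`, `score`, `label`.
#' @return Number of records inserted.
#' @export
add_areas <- function(store, user, dataset_id, areas) {
  check_store(store)
  row <- dataset_row(store, dataset_id)
  require_owner(store, dataset_id, user, "add features")
  if (row$content_kind != "area") abort_kind(paste0("dataset ", dataset_id, " holds motifs, not areas"))
  areas <- tibble::as_tibble(areas)
  validate_intervals(areas, "areas")
  n <- nrow(areas)
  if (n == 0L) return(0L)
  ids <- seq.int(store$next_area_id, length.out = n)
  store$next_area_id <- store$next_area_id + n
  store$area <- dplyr::bind_rows(store$area, tibble::tibble(
    area_id = as.integer(ids), dataset_id = dataset_id,
    seq_region = as.character(areas$seq_region),
    start = as.double(areas$start), end = as.double(areas$end),
    strand = if ("strand" %in% names(areas)) as.character(areas$strand) else NA_character_,
    score = if ("score" %in% names(areas)) as.double(areas$score) else NA_real_,
    label = if ("label" %in% names(areas)) as.character(areas$label) else NA_character_
  ))
  log_op(user, "add_areas", dataset_id, n)
  n
}

#' @rdname add_areas
#' @param instances Tibble with columns `seq_region`, `start`, `end`,
#'   `strand`, `weight_score`, `p_value`.
#' @export
add_motif_instances <- function(store, user, dataset_id, instances) {
  check_store(store)
  row <- dataset_row(store, dataset_id)
  require_owner(store, dataset_id, user, "add features")
  if (row$content_kind != "motif") abort_kind(paste0("dataset ", dataset_id, " holds areas, not motifs"))
  instances <- tibble::as_tibble(instances)
  validate_intervals(instances, "motif instances")
  n <- nrow(instances)
  if (n == 0L) return(0L)
  ids <- seq.int(store$next_motif_id, length.out = n)
  store$next_motif_id <- store$next_motif_id + n
  store$motif <- dplyr::bind_rows(store$motif, tibble::tibble(
    motif_id = as.integer(ids), dataset_id = dataset_id,
    seq_region = as.character(instances$seq_region),
    start = as.double(instances$start), end = as.double(instances$end),
    strand = if ("strand" %in% names(instances)) as.character(instances$strand) else NA_character_,
    weight_score = if ("weight_score" %in% names(instances)) as.double(instances$weight_score) else NA_real_,
    p_value = if ("p_value" %in% names(instances)) as.double(instances$p_value) else NA_real_
  ))
  log_op(user, "add_motif_instances", dataset_id, n)
  n
}

#' List the datasets a user can see
#'
#' The visible set is exactly the public datasets plus those the user
#' holds a grant on; the anonymous user sees public datasets only.
#'
#' @inheritParams can_read
#' @return A tibble of dataset rows, ordered by `dataset_id`.
#' @export
visible_datasets <- function(store, user) {
  check_store(store)
  granted <- store$access_grant$dataset_id[store$access_grant$user == user]
  store$dataset |>
    dplyr::filter(.data$is_public | .data$dataset_id %in% granted) |>
    dplyr::arrange(.data$dataset_id)
}

#' Is a stored result visible to a user?
#'
#' A result row (intersection or gene-map row) is visible iff the user
#' can read every dataset it references — both datasets of an
#' intersection, or the area's dataset for a gene-map row.  Results on
#' datasets that are made public thereby become public themselves.
#'
#' @inheritParams can_read
#' @param record A one-row data frame: an `area_intersection` row (has
#'   `dataset1_id`/`dataset2_id`), a `motif_intersection` row (has
#'   `area_dataset_id`/`motif_dataset_id`) or an `area_gene_map` row
#'   (has `area_dataset_id` only).
#' @return Logical scalar.
#' @export
result_visible <- function(store, user, record) {
  check_store(store)
  nm <- names(record)
  refs <- if (all(c("dataset1_id", "dataset2_id") %in% nm)) {
    c(record$dataset1_id, record$dataset2_id)
  } else if (all(c("area_dataset_id", "motif_dataset_id") %in% nm)) {
    c(record$area_dataset_id, record$motif_dataset_id)
  } else if ("area_dataset_id" %in% nm) {
    record$area_dataset_id
  } else {
    abort_validation("record is not an intersection or gene-map row")
  }
  all(vapply(unique(refs), function(d) can_read(store, user, d), logical(1)))
}

job_key <- function(procedure, ds1, ds2) {
  k1 <- as.character(ds1); k2 <- as.character(ds2)
  if (procedure == "area_area" && k2 < k1) { tmp <- k1; k1 <- k2; k2 <- tmp }
  list(key1 = k1, key2 = k2)
}

#' Record a dataset-level job, skipping duplicates
#'
#' The registry memoises completed (procedure, dataset-pair) jobs so an
#' intersection or mapping already in the store is never recomputed or
#' duplicated.  The pair key is direction-insensitive for area–area
#' jobs.
#'
#' @param store A [regstore()] object.
#' @param procedure One of `"area_area"`, `"area_motif"`, `"gene_map"`.
#' @param ds1,ds2 Dataset ids (for `gene_map`, `ds2` is the
#'   gene-annotation tag).
#' @return `"new"` if the job was recorded now, `"already_done"` if it
#'   was present.
#' @export
register_job <- function(store, procedure = c("area_area", "area_motif", "gene_map"),
                         ds1, ds2) {
  check_store(store)
  procedure <- match.arg(procedure)
  k <- job_key(procedure, ds1, ds2)
  jr <- store$job_registry
  hit <- jr$procedure == procedure & jr$key1 == k$key1 & jr$key2 == k$key2
  if (any(hit)) return("already_done")
  store$job_registry <- dplyr::bind_rows(jr, tibble::tibble(
    procedure = procedure, key1 = k$key1, key2 = k$key2
  ))
  "new"
}
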