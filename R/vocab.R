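# The generalized data converter: hand-crafted conversion maps, projection
# of per-dataset annotations into a super-set keypoint space with extended
# visibility flags, and dataset merging.
#
# Extended visibility flags: -1 = keypoint not defined in the source
# dataset's vocabulary (coordinates ignored by contract and written as 0,0),
# 0 = defined but not labeled, 1 = labeled but not visible, 2 = labeled and
# visible. The distinction between "not defined" (-1) and "not annotated"
# (0) matters downstream: only -1 keypoints are masked from the loss.

#' Build a conversion map
#'
#' A conversion map records, per source dataset, the hand-crafted mapping
#' from local keypoint names to super-set names. Identity entries may be
#' omitted. The mapping must be injective within a dataset: two local
#' names may not map to one super-set name.
#'
#' @param ... Named arguments, one per dataset: each a named character
#'   vector `local_name = "superset_name"` (possibly empty), or a list
#'   coercible to one.
#' @return A named list of class `conversion_map`.
#' @export
conversion_map <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && is.null(names(maps)) && is.list(maps[[1]]) &&
      !is.null(names(maps[[1]]))) {
    maps <- maps[[1]]
  }
  if (is.null(names(maps)) || any(names(maps) == "")) {
    abort("every dataset in a conversion map must be named")
  }
  maps <- lapply(maps, function(m) {
    m <- unlist(m)
    if (length(m) == 0) return(character())
    storage.mode(m) <- "character"
    m
  })
  for (ds in names(maps)) {
    m <- maps[[ds]]
    if (anyDuplicated(m)) {
      tgt <- m[duplicated(m)][1]
      locs <- names(m)[m == tgt]
      abort(sprintf(
        "dataset '%s': local keys '%s' and '%s' both map to '%s'",
        ds, locs[1], locs[2], tgt))
    }
  }
  structure(maps, class = "conversion_map")
}

# Effective local -> superset lookup for one dataset (identity for names
# not in the map). Errors on names that are neither mapped nor super-set
# members when `superset` is given.
resolve_names <- function(local, map, superset = NULL) {
  out <- local
  hit <- local %in% names(map)
  out[hit] <- unname(map[local[hit]])
  if (!is.null(superset)) {
    bad <- setdiff(out, superset)
    if (length(bad) > 0) {
      abort(paste0("unmapped local keypoint name(s): ",
                   paste(unique(local[out %in% bad]), collapse = ", ")))
    }
  }
  out
}

#' Build the super-set keypoint vocabulary
#'
#' The super-set is the union of all target names across datasets, ordered
#' by first appearance in the declared dataset order; within one dataset,
#' mapped targets appear in the map's declared order followed by that
#' dataset's identity names (if `local_vocabs` is supplied).
#'
#' @param maps A [conversion_map()].
#' @param local_vocabs Optional named list of each dataset's full local
#'   vocabulary (so identity-mapped names omitted from the map enter the
#'   union too).
#' @return Character vector of unique super-set keypoint names.
#' @export
build_superset <- function(maps, local_vocabs = NULL) {
  if (!inherits(maps, "conversion_map")) maps <- conversion_map(maps)
  targets <- character()
  for (ds in names(maps)) {
    tgt <- unname(maps[[ds]])
    if (!is.null(local_vocabs[[ds]])) {
      extra <- resolve_names(local_vocabs[[ds]], maps[[ds]])
      tgt <- c(tgt, extra)
    }
    targets <- c(targets, tgt)
  }
  unique(targets)
}

#' Project annotations into the super-set keypoint space
#'
#' Renames covered keypoints to their super-set names (coordinates
#' unchanged, local COCO flags 0/1/2 passing through) and adds one row per
#' super-set keypoint absent from the dataset's vocabulary, with flag -1
#' and coordinates 0. Unmapped local names are an error, never silently
#' dropped.
#'
#' @param annotations Tibble with columns `image_id`, `keypoint`, `x`,
#'   `y`, `flag` (and optionally `dataset_id`).
#' @param map Named character vector `local -> superset` for this dataset
#'   (identity entries may be omitted), or a [conversion_map()] plus
#'   `dataset` naming which entry to use.
#' @param superset Character vector from [build_superset()].
#' @param dataset When `map` is a [conversion_map()], the dataset id.
#' @return Tibble with one row per image x super-set keypoint, columns
#'   `dataset_id`, `image_id`, `keypoint`, `x`, `y`, `flag`; attribute
#'   `keypoints` holds the super-set order.
#' @export
project_annotations <- function(annotations, map, superset, dataset = NULL) {
  if (inherits(map, "conversion_map")) {
    if (is.null(dataset)) {
      if (length(map) != 1) abort("specify `dataset` to pick a map entry")
      dataset <- names(map)[1]
    }
    map <- map[[dataset]]
  }
  ds <- dataset %||% (if ("dataset_id" %in% names(annotations))
    annotations$dataset_id[1] else "dataset")
  ann <- tibble::as_tibble(annotations)
  stopifnot(all(c("image_id", "keypoint", "x", "y", "flag") %in% names(ann)))
  if (!all(ann$flag %in% c(0L, 1L, 2L))) {
    abort("local COCO flags must be in {0, 1, 2}")
  }
  ann$.superset <- resolve_names(ann$keypoint, map, superset)

  full <- tidyr::expand_grid(image_id = unique(ann$image_id),
                             keypoint = superset)
  out <- full |>
    dplyr::left_join(
      dplyr::select(ann, "image_id", keypoint = ".superset",
                    "x", "y", "flag"),
      by = c("image_id", "keypoint")) |>
    dplyr::mutate(
      flag = as.integer(ifelse(is.na(.data$flag), -1L, .data$flag)),
      x = ifelse(.data$flag == -1L, 0, .data$x),
      y = ifelse(.data$flag == -1L, 0, .data$y),
      dataset_id = ds, .before = 1)
  out$keypoint <- factor(out$keypoint, levels = superset)
  out <- dplyr::arrange(out, .data$image_id, .data$keypoint)
  out$keypoint <- as.character(out$keypoint)
  attr(out, "keypoints") <- superset
  out
}

#' Invert a projection for covered keypoints
#'
#' Recovers the original local annotations (names, coordinates, flags) of
#' the keypoints the dataset covers; flag -1 rows are dropped.
#'
#' @inheritParams project_annotations
#' @param projected Output of [project_annotations()].
#' @return Tibble of local annotations.
#' @export
unproject_annotations <- function(projected, map) {
  if (inherits(map, "conversion_map")) map <- map[[1]]
  inv <- setNames(names(map), unname(map))
  projected |>
    dplyr::filter(.data$flag >= 0) |>
    dplyr::mutate(keypoint = ifelse(.data$keypoint %in% names(inv),
                                    unname(inv[.data$keypoint]),
                                    .data$keypoint)) |>
    dplyr::select("image_id", "keypoint", "x", "y", "flag")
}

#' Merge projected datasets
#'
#' Concatenates annotation collections that share one super-set
#' vocabulary; per-image provenance is retained in `dataset_id`.
#'
#' @param ... Projected annotation tibbles (or one list of them).
#' @return A single tibble with attribute `keypoints`.
#' @export
merge_datasets <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  stopifnot(length(inputs) >= 1)
  vocab <- attr(inputs[[1]], "keypoints")
  for (d in inputs) {
    if (!identical(attr(d, "keypoints"), vocab)) {
      abort("vocabulary mismatch: all inputs must share one super-set")
    }
  }
  out <- dplyr::bind_rows(inputs)
  attr(out, "keypoints") <- vocab
  out
}

# ---- COCO-keypoints JSON dialect -------------------------------------------
# Standard COCO keypoint triplets [x1, y1, v1, ...] with v extended to
# allow -1; a top-level "superset_keypoints" field records the vocabulary
# order, and every annotation carries the full super-set length.

#' Write projected annotations as COCO-dialect JSON
#'
#' @param projected Tibble from [project_annotations()] or
#'   [merge_datasets()] (attribute `keypoints` required unless `superset`
#'   is given).
#' @param path Output file.
#' @param superset Vocabulary order override.
#' @param image_size `c(height, width)` recorded per image.
#' @return `path`, invisibly.
#' @export
write_coco <- function(projected, path, superset = NULL,
                       image_size = c(64L, 64L)) {
  superset <- superset %||% attr(projected, "keypoints")
  if (is.null(superset)) abort("super-set vocabulary unknown")
  ids <- unique(projected$image_id)
  ds_of <- projected |>
    dplyr::distinct(.data$image_id, .data$dataset_id)
  anns <- lapply(seq_along(ids), function(i) {
    rows <- projected[projected$image_id == ids[i], ]
    rows <- rows[match(superset, rows$keypoint), ]
    flat <- as.numeric(rbind(rows$x, rows$y, rows$flag))
    list(id = i, image_id = i, category_id = 1L,
         keypoints = flat,
         num_keypoints = sum(rows$flag > 0),
         dataset_id = ds_of$dataset_id[ds_of$image_id == ids[i]][1])
  })
  obj <- list(
    info = list(description = "panpose super-set annotations"),
    superset_keypoints = superset,
    images = lapply(seq_along(ids), function(i)
      list(id = i, file_name = paste0(ids[i], ".png"),
           height = image_size[1], width = image_size[2])),
    annotations = anns,
    categories = list(list(id = 1L, name = "animal",
                           keypoints = superset, skeleton = list()))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read COCO-dialect JSON annotations
#'
#' @param path JSON file written by [write_coco()] (or standard COCO
#'   keypoints with flags >= 0).
#' @return Projected-annotation tibble with attribute `keypoints`.
#' @export
read_coco <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  superset <- obj$superset_keypoints %||% obj$categories$keypoints[[1]]
  imgs <- obj$images
  imgs$name <- sub("\\.png$", "", imgs$file_name)
  anns <- obj$annotations
  rows <- lapply(seq_len(nrow(anns)), function(i) {
    flat <- anns$keypoints[[i]]
    m <- matrix(flat, nrow = 3)
    tibble::tibble(
      dataset_id = if ("dataset_id" %in% names(anns))
        anns$dataset_id[i] else "dataset",
      image_id = imgs$name[match(anns$image_id[i], imgs$id)],
      keypoint = superset,
      x = m[1, ], y = m[2, ], flag = as.integer(m[3, ]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "keypoints") <- superset
  out
}

#' Write or read a conversion map as JSON
#'
#' Serialized as `{dataset_id: {local_name: superset_name}}`; identity
#' entries may be omitted.
#'
#' @param maps A [conversion_map()].
#' @param path JSON file.
#' @return `path` invisibly, or the [conversion_map()].
#' @export
write_conversion_map <- function(maps, path) {
  jsonlite::write_json(lapply(unclass(maps), as.list), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_conversion_map
#' @export
read_conversion_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  conversion_map(lapply(obj, function(m) unlist(m) %||% character()))
}
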