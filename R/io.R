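# Disk formats: wide-CSV pose tracks, PNG frame directories, dataset
# bundles (PNG images + COCO-dialect JSON + ground-truth CSV).

#' Write or read a pose track as wide CSV
#'
#' Columns: `frame`, then `<kp>_x`, `<kp>_y`, `<kp>_conf` per keypoint.
#'
#' @param track Pose track tibble (`frame`, `keypoint`, `x`, `y`,
#'   `confidence`).
#' @param path CSV file.
#' @param fps Frame rate stored back on read via attribute (optional
#'   header comment is not used; pass `fps` to [read_track()]).
#' @return `path` invisibly / the track tibble.
#' @export
write_track <- function(track, path) {
  assert_track(track)
  conf <- track[["confidence"]] %||% rep(1, nrow(track))
  long <- track |>
    dplyr::mutate(conf = conf) |>
    dplyr::select("frame", "keypoint", "x", "y", "conf")
  wide <- tidyr::pivot_wider(long, names_from = "keypoint",
                             values_from = c("x", "y", "conf"),
                             names_glue = "{keypoint}_{.value}")
  # order columns keypoint-major: kp_x, kp_y, kp_conf
  kps <- unique(track$keypoint)
  cols <- c("frame", as.vector(t(outer(kps, c("_x", "_y", "_conf"),
                                       paste0))))
  utils::write.csv(wide[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, fps = NULL) {
  wide <- utils::read.csv(path, check.names = FALSE)
  kps <- unique(sub("_(x|y|conf)$", "",
                    setdiff(names(wide), "frame")))
  out <- purrr::map_dfr(kps, function(k) {
    tibble::tibble(frame = wide$frame, keypoint = k,
                   x = wide[[paste0(k, "_x")]],
                   y = wide[[paste0(k, "_y")]],
                   confidence = wide[[paste0(k, "_conf")]])
  }) |>
    dplyr::arrange(.data$frame, .data$keypoint)
  if (!is.null(fps)) attr(out, "fps") <- fps
  out
}

#' Write or read video frames as a PNG directory
#'
#' Frames are written as `frame_%06d.png` (the canonical video layout).
#'
#' @param frames List of grayscale matrices (or a `pose_video`).
#' @param dir Directory (created if needed).
#' @return `dir` invisibly / a named list of matrices.
#' @export
write_frames <- function(frames, dir) {
  if (inherits(frames, "pose_video")) frames <- frames$frames
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no frames found in %s", dir))
  out <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  names(out) <- sub("\\.png$", "", basename(files))
  out
}

#' Write or read a generated dataset bundle
#'
#' Layout: `images/<image_id>.png`, `annotations.json` (COCO dialect over
#' the local vocabulary), `truth.csv` (canonical ground truth).
#'
#' @param dataset A `pose_dataset` from [generate_dataset()].
#' @param dir Directory.
#' @return `dir` invisibly / a list with `images`, `annotations`,
#'   `truth`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pose_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(dataset$images)) {
    png::writePNG(dataset$images[[id]],
                  file.path(dir, "images", paste0(id, ".png")))
  }
  # local annotations serialize through the COCO dialect with the local
  # vocabulary as the keypoint order
  ann <- dataset$annotations
  attr(ann, "keypoints") <- dataset$keypoints
  write_coco(ann, file.path(dir, "annotations.json"),
             superset = dataset$keypoints,
             image_size = dataset$spec$image_size)
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ann <- read_coco(file.path(dir, "annotations.json"))
  files <- list.files(file.path(dir, "images"), pattern = "\\.png$",
                      full.names = TRUE)
  images <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  names(images) <- sub("\\.png$", "", basename(files))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    tibble::as_tibble(utils::read.csv(truth_path))
  }
  list(images = images, annotations = ann, truth = truth)
}
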