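# Evaluation metrics: RMSE, normalized error, OKS and mAP with per-keypoint
# sigmas, convex-hull body area, jitter, keypoint dropping, and
# adaptation/robustness gains.

#' Per-keypoint OKS falloff constants
#'
#' @param values Named numeric vector of falloff constants k_i (> 0).
#' @param default Constant for keypoint names not listed.
#' @return Object of class `sigma_table`.
#' @export
sigma_table <- function(values = numeric(), default = 0.1) {
  values <- unlist(values)
  stopifnot(all(values > 0), default > 0)
  structure(list(values = values, default = default),
            class = "sigma_table")
}

#' @rdname sigma_table
#' @details `sigma_table_mouse()` uses 0.1 for every keypoint (the lab
#'   mouse convention); `sigma_table_quadruped()` carries the per-keypoint
#'   constants for the 39 named quadruped keypoints (0.067 for any other
#'   name).
#' @export
sigma_table_mouse <- function() sigma_table(default = 0.1)

#' @rdname sigma_table
#' @export
sigma_table_quadruped <- function() {
  sigma_table(c(
    nose = 0.026, upper_jaw = 0.067, lower_jaw = 0.067,
    mouth_end_right = 0.067, mouth_end_left = 0.067,
    right_eye = 0.025, right_earbase = 0.067, right_earend = 0.067,
    right_antler_base = 0.067, right_antler_end = 0.067,
    left_eye = 0.025, left_earbase = 0.067, left_earend = 0.067,
    left_antler_base = 0.067, left_antler_end = 0.067,
    neck_base = 0.035, neck_end = 0.067,
    throat_base = 0.067, throat_end = 0.067,
    back_base = 0.067, back_end = 0.067, back_middle = 0.035,
    tail_base = 0.067, tail_end = 0.079,
    front_left_thai = 0.072, front_left_knee = 0.062,
    front_left_paw = 0.079, front_right_thigh = 0.072,
    front_right_knee = 0.062, front_right_paw = 0.089,
    back_left_paw = 0.107, back_left_thigh = 0.107,
    back_right_thai = 0.087, back_left_knee = 0.087,
    back_right_knee = 0.089, back_right_paw = 0.067,
    belly_bottom = 0.067, body_middle_right = 0.067,
    body_middle_left = 0.067), default = 0.067)
}

sigma_of <- function(sigmas, keypoints) {
  if (!inherits(sigmas, "sigma_table")) sigmas <- sigma_table(sigmas)
  out <- rep(sigmas$default, length(keypoints))
  hit <- keypoints %in% names(sigmas$values)
  out[hit] <- unname(sigmas$values[keypoints[hit]])
  out
}

#' Write or read a sigma table as JSON
#'
#' @param sigmas A [sigma_table()].
#' @param path JSON file.
#' @return `path` invisibly / a `sigma_table`.
#' @export
write_sigma_table <- function(sigmas, path) {
  jsonlite::write_json(list(values = as.list(sigmas$values),
                            default = sigmas$default),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sigma_table
#' @export
read_sigma_table <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigma_table(unlist(o$values) %||% numeric(), o$default)
}

# Pair predictions with ground truth by keypoint name.
pair_by_name <- function(predictions, truth) {
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(predictions),
                  dplyr::any_of(c("image_id", "frame")),
                  "keypoint", px = "x", py = "y"),
    dplyr::select(tibble::as_tibble(truth),
                  dplyr::any_of(c("image_id", "frame", "flag")),
                  "keypoint", tx = "x", ty = "y"),
    by = intersect(intersect(names(predictions), names(truth)),
                   c("image_id", "frame", "keypoint")))
}

#' Root mean squared error in pixels
#'
#' Root of the mean squared Euclidean distance over labeled keypoints.
#' No confidence filtering is applied: every prediction, including
#' outliers, is penalized.
#'
#' @param predictions,truth Tibbles with `keypoint`, `x`, `y` (and
#'   optionally `image_id`/`frame` to pair on). Truth rows with a `flag`
#'   column keep only flags > 0.
#' @return RMSE in px.
#' @export
pose_rmse <- function(predictions, truth) {
  d <- pair_by_name(predictions, truth)
  if ("flag" %in% names(d)) d <- d[d$flag > 0, ]
  d <- d[is.finite(d$tx) & is.finite(d$ty), ]
  if (nrow(d) == 0) abort("no labeled keypoints to evaluate")
  sqrt(mean((d$px - d$tx)^2 + (d$py - d$ty)^2))
}

#' Normalized error
#'
#' RMSE (confidence cutoff 0, all predictions included) divided by the
#' ground-truth distance between two reference keypoints (e.g., eye to
#' nose), averaged across images when several are present.
#'
#' @inheritParams pose_rmse
#' @param reference Character vector of two ground-truth keypoint names.
#' @return Unitless normalized error.
#' @export
normalized_error <- function(predictions, truth, reference) {
  stopifnot(length(reference) == 2)
  tr <- tibble::as_tibble(truth)
  if ("flag" %in% names(tr)) tr <- tr[tr$flag > 0, ]
  wide <- tr[tr$keypoint %in% reference, ]
  if (!all(reference %in% wide$keypoint)) {
    abort("reference keypoints must be visible in the ground truth")
  }
  grp <- intersect(names(wide), c("image_id", "frame"))
  wide <- tidyr::pivot_wider(
    dplyr::select(wide, dplyr::all_of(c(grp, "keypoint", "x", "y"))),
    names_from = "keypoint", values_from = c("x", "y"))
  ref <- mean(sqrt(
    (wide[[paste0("x_", reference[1])]] -
       wide[[paste0("x_", reference[2])]])^2 +
    (wide[[paste0("y_", reference[1])]] -
       wide[[paste0("y_", reference[2])]])^2))
  if (!is.finite(ref) || ref == 0) abort("reference distance is zero")
  pose_rmse(predictions, truth) / ref
}

#' Object keypoint similarity
#'
#' `OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) delta(v_i > 0) /
#' sum_i delta(v_i > 0)` where d_i is the Euclidean prediction error,
#' v_i the ground-truth visibility, s the object scale (square root of
#' the bounding-box area) and k_i the per-keypoint falloff constant.
#'
#' @inheritParams pose_rmse
#' @param sigmas A [sigma_table()].
#' @param scale Object scale s; default: sqrt of the area of the
#'   ground-truth bounding box (visible keypoints).
#' @return OKS in `[0, 1]`.
#' @export
oks <- function(predictions, truth, sigmas = sigma_table_mouse(),
                scale = NULL) {
  d <- pair_by_name(predictions, truth)
  if (!"flag" %in% names(d)) d$flag <- 2L
  vis <- d[d$flag > 0, ]
  if (nrow(vis) == 0) abort("OKS undefined: no visible ground-truth keypoint")
  if (is.null(scale)) {
    scale <- sqrt(diff(range(vis$tx)) * diff(range(vis$ty)))
  }
  if (!is.finite(scale) || scale <= 0) abort("object scale must be > 0")
  k <- sigma_of(sigmas, vis$keypoint)
  d2 <- (vis$px - vis$tx)^2 + (vis$py - vis$ty)^2
  mean(exp(-d2 / (2 * scale^2 * k^2)))
}

# COCO-style AP at one OKS threshold: detections ranked by score, each a
# TP iff its image's OKS reaches the threshold; 101-point interpolated
# precision averaged over recall levels.
ap_at <- function(oks_values, scores, thr) {
  ord <- order(-scores, seq_along(scores))
  tp <- oks_values[ord] >= thr
  fp <- !tp
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / length(oks_values)
  precision <- ctp / (ctp + cfp)
  # monotone precision envelope
  for (i in rev(seq_len(length(precision) - 1))) {
    precision[i] <- max(precision[i], precision[i + 1])
  }
  rec_thrs <- seq(0, 1, 0.01)
  idx <- findInterval(rec_thrs, recall, left.open = TRUE) + 1
  p <- ifelse(idx <= length(precision), precision[idx], 0)
  mean(p)
}

#' Mean average precision over OKS thresholds
#'
#' Single-instance COCO-protocol mAP: per-image OKS between the one
#' prediction set and the one ground truth, detections ranked by score
#' (mean keypoint confidence), average precision computed per OKS
#' threshold with 101-point interpolation and averaged over thresholds
#' 0.50:0.05:0.95. Reported on the 0-100 scale.
#'
#' @param predictions Tibble: `image_id`, `keypoint`, `x`, `y` and
#'   optionally `confidence`.
#' @param truth Tibble: `image_id`, `keypoint`, `x`, `y`, `flag`.
#' @param sigmas A [sigma_table()].
#' @param thresholds OKS thresholds.
#' @param scales Optional named vector of per-image object scales.
#' @return mAP in `[0, 100]`.
#' @export
map_score <- function(predictions, truth, sigmas = sigma_table_mouse(),
                      thresholds = seq(0.50, 0.95, 0.05), scales = NULL) {
  ids <- unique(truth$image_id)
  if (length(ids) == 0) abort("empty ground truth")
  per_image <- vapply(ids, function(id) {
    p <- predictions[predictions$image_id == id, ]
    t <- truth[truth$image_id == id, ]
    c(oks(p, t, sigmas, scale = scales[[id]] %||% NULL),
      if ("confidence" %in% names(p)) mean(p$confidence) else 1)
  }, numeric(2))
  aps <- vapply(thresholds, function(thr)
    ap_at(per_image[1, ], per_image[2, ], thr), numeric(1))
  100 * mean(aps)
}

#' Convex-hull body area per frame
#'
#' Area of the convex hull of the keypoints surviving the confidence
#' cutoff, per frame; frames with fewer than 3 surviving points get area
#' 0 and are flagged degenerate.
#'
#' @param track Pose track tibble: `frame`, `keypoint`, `x`, `y`,
#'   `confidence`.
#' @param cutoff Confidence cutoff (keypoints with confidence >= cutoff
#'   survive).
#' @return Tibble: `frame`, `area`, `degenerate`.
#' @export
hull_area_series <- function(track, cutoff = 0.1) {
  assert_track(track)
  conf <- track[["confidence"]] %||% rep(1, nrow(track))
  track |>
    dplyr::mutate(.conf = conf) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      area = {
        keep <- .data$.conf >= cutoff
        hull_area(.data$x[keep], .data$y[keep])
      },
      degenerate = sum(.data$.conf >= cutoff &
                         is.finite(.data$x) & is.finite(.data$y)) < 3)
}

#' Jitter of a pose track
#'
#' Per keypoint: frame-to-frame displacement magnitudes (non-signed
#' speeds), centered by subtracting their mean; the jitter J is the mean
#' of the absolute centered speeds. A constant-velocity track therefore
#' has jitter 0.
#'
#' @param track Pose track tibble (>= 3 frames).
#' @return Tibble: `keypoint`, `jitter`.
#' @export
pose_jitter <- function(track) {
  assert_track(track)
  if (dplyr::n_distinct(track$frame) < 3) {
    abort("jitter needs at least 3 frames")
  }
  track |>
    dplyr::group_by(.data$keypoint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(jitter = {
      sp <- sqrt(diff(.data$x)^2 + diff(.data$y)^2)
      mean(abs(sp - mean(sp)))
    })
}

#' @rdname pose_jitter
#' @return `jitter_score()`: the aggregate (mean over keypoints) jitter.
#' @export
jitter_score <- function(track) {
  mean(pose_jitter(track)$jitter)
}

#' Keypoint dropping
#'
#' Counts, per frame, the keypoints whose confidence is strictly below
#' the threshold (0.1 is the bottom-up convention, 0.05 top-down).
#'
#' @param track Pose track tibble with `confidence`.
#' @param threshold Confidence threshold.
#' @return Tibble `frame`, `dropped`; attribute `total` holds the sum.
#' @export
keypoint_drop <- function(track, threshold = 0.1) {
  assert_track(track)
  stopifnot("confidence" %in% names(track))
  out <- track |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(dropped = sum(.data$confidence < threshold))
  attr(out, "total") <- sum(out$dropped)
  out
}

#' Adaptation and robustness gain
#'
#' Adaptation gain is the post-minus-pre change in mAP on the video the
#' model adapted to; robustness gain is the same change averaged over all
#' videos of the set. Negative numbers mean degradation.
#'
#' @param pre,post Tibbles `video_id`, `map` evaluated on identical
#'   frames.
#' @param adapted Video id the model was adapted on.
#' @return List of class `gain_report`: `per_video` tibble (video_id,
#'   pre, post, gain), `adaptation_gain`, `robustness_gain`.
#' @export
gains <- function(pre, post, adapted) {
  d <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(pre), pre = "map"),
    dplyr::rename(tibble::as_tibble(post), post = "map"),
    by = "video_id") |>
    dplyr::mutate(gain = .data$post - .data$pre)
  if (!adapted %in% d$video_id) {
    abort(sprintf("adapted video '%s' absent from results", adapted))
  }
  structure(list(per_video = d,
                 adaptation_gain = d$gain[d$video_id == adapted],
                 robustness_gain = mean(d$gain),
                 adapted = adapted),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf(
    "<gain_report: adaptation %+0.3f on '%s', robustness %+0.3f over %d videos>\n",
    x$adaptation_gain, x$adapted, x$robustness_gain, nrow(x$per_video)))
  invisible(x)
}
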