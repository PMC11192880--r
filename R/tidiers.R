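# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pose model's training history
#'
#' @param x A `pose_model`.
#' @param ... Unused.
#' @return Tibble: `step`, `loss`.
#' @method tidy pose_model
#' @export
tidy.pose_model <- function(x, ...) {
  x$history
}

#' One-row model summary
#'
#' @param x A `pose_model`.
#' @param ... Unused.
#' @return Tibble: keypoints, channels, parameters, steps, final loss.
#' @method glance pose_model
#' @export
glance.pose_model <- function(x, ...) {
  tibble::tibble(
    n_keypoints = length(x$config$keypoints),
    channels = x$config$channels,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    steps_trained = nrow(x$history),
    final_loss = if (nrow(x$history) > 0)
      x$history$loss[nrow(x$history)] else NA_real_)
}

#' Tidy a keypoint-matching result
#'
#' @param x A `keypoint_match`.
#' @param ... Unused.
#' @return The conversion table tibble.
#' @method tidy keypoint_match
#' @export
tidy.keypoint_match <- function(x, ...) x$table

#' @method glance keypoint_match
#' @export
glance.keypoint_match <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$table), n_images = x$n_images,
                 mean_affinity = mean(x$table$affinity))
}

#' Tidy an action-classification result
#'
#' @param x An `action_classifier_result`.
#' @param ... Unused.
#' @return Per-fold, per-class F1 tibble.
#' @method tidy action_classifier_result
#' @export
tidy.action_classifier_result <- function(x, ...) x$per_fold

#' @method glance action_classifier_result
#' @export
glance.action_classifier_result <- function(x, ...) {
  tibble::tibble(window = x$window,
                 macro_f1 = mean(x$f1$f1, na.rm = TRUE))
}

#' Tidy stride statistics
#'
#' @param x A `stride_stats`.
#' @param ... Unused.
#' @return The per-stride tibble.
#' @method tidy stride_stats
#' @export
tidy.stride_stats <- function(x, ...) x$strides

#' @method glance stride_stats
#' @export
glance.stride_stats <- function(x, ...) {
  tibble::tibble(n_strides = nrow(x$strides),
                 mean_stride_px = mean(x$strides$length_px),
                 n_stances = nrow(x$stances),
                 mean_stance_frames = mean(x$stances$duration_frames),
                 n_contacts = sum(x$contacts$n_contacts))
}

#' Tidy a gain report
#'
#' @param x A `gain_report`.
#' @param ... Unused.
#' @return Per-video tibble with pre/post/gain columns.
#' @method tidy gain_report
#' @export
tidy.gain_report <- function(x, ...) x$per_video

#' @method glance gain_report
#' @export
glance.gain_report <- function(x, ...) {
  tibble::tibble(adaptation_gain = x$adaptation_gain,
                 robustness_gain = x$robustness_gain)
}
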