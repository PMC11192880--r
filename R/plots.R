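# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_path facet_wrap labs scale_fill_gradient theme_minimal
#'   geom_vline scale_y_reverse
#' @export
ggplot2::autoplot

#' Plot a training-loss history
#'
#' @param object A `pose_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pose_model
#' @export
autoplot.pose_model <- function(object, ...) {
  ggplot(object$history, aes(x = .data$step, y = .data$loss)) +
    geom_line(color = "steelblue") +
    labs(x = "training step", y = "masked loss",
         title = "Training history") +
    theme_minimal()
}

#' Plot a pose track
#'
#' One path per keypoint in image coordinates (y axis reversed to match
#' the image convention).
#'
#' @param track Pose track tibble.
#' @return A ggplot.
#' @export
plot_track <- function(track) {
  assert_track(track)
  ggplot(track, aes(x = .data$x, y = .data$y, color = .data$keypoint)) +
    geom_path(alpha = 0.7) +
    scale_y_reverse() +
    labs(x = "x (px)", y = "y (px)", title = "Keypoint trajectories") +
    theme_minimal()
}

#' Plot an affinity matrix
#'
#' @param object A `keypoint_match`.
#' @param ... Unused.
#' @return A ggplot heat map of the affinity matrix.
#' @method autoplot keypoint_match
#' @export
autoplot.keypoint_match <- function(object, ...) {
  A <- object$affinity
  d <- tidyr::expand_grid(model = rownames(A) %||%
                            paste0("m", seq_len(nrow(A))),
                          dataset = colnames(A) %||%
                            paste0("d", seq_len(ncol(A))))
  d$affinity <- as.vector(t(A))
  ggplot(d, aes(x = .data$dataset, y = .data$model,
                fill = .data$affinity)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        limits = c(0, 1)) +
    labs(title = "Keypoint matching affinity") +
    theme_minimal()
}

#' Plot detected gait events over relative hoof trajectories
#'
#' @param object A `gait_events` tibble.
#' @param track The pose track the events were detected on.
#' @param back_keypoint Back reference keypoint name.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_events
#' @export
autoplot.gait_events <- function(object, track = NULL,
                                 back_keypoint = "back", ...) {
  if (is.null(track)) {
    return(ggplot(object, aes(x = .data$frame, y = .data$keypoint,
                              color = .data$event)) +
             geom_point() +
             labs(title = "Gait events") + theme_minimal())
  }
  hooves <- unique(object$keypoint)
  back_x <- track$x[track$keypoint == back_keypoint]
  rel <- purrr::map_dfr(hooves, function(h) {
    tibble::tibble(frame = sort(unique(track$frame)),
                   keypoint = h,
                   rel_x = track$x[track$keypoint == h] - back_x)
  })
  ggplot(rel, aes(x = .data$frame, y = .data$rel_x)) +
    geom_line(color = "grey40") +
    geom_vline(data = object,
               aes(xintercept = .data$frame, color = .data$event),
               alpha = 0.6) +
    facet_wrap(~keypoint) +
    labs(x = "frame", y = "fore-aft position relative to back (px)",
         title = "Gait events") +
    theme_minimal()
}

#' Plot convex-hull body-area series
#'
#' @param tracks Named list of pose tracks (e.g., before/after
#'   adaptation).
#' @param cutoff Confidence cutoff for the hull.
#' @return A ggplot of A_body over time per track.
#' @export
plot_hull_series <- function(tracks, cutoff = 0.1) {
  d <- purrr::imap_dfr(tracks, function(tr, nm)
    dplyr::mutate(hull_area_series(tr, cutoff), track = nm))
  ggplot(d, aes(x = .data$frame, y = .data$area, color = .data$track)) +
    geom_line() +
    labs(x = "frame", y = "convex-hull area (px^2)",
         title = "Body-area smoothness") +
    theme_minimal()
}
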