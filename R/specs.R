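# Spec constructors for the synthetic-data generators.

# Canonical 12-keypoint vocabulary: body-frame coordinates on an ellipse
# body, x forward (toward the nose), y to the animal's right.
.default_body <- function() {
  m <- rbind(
    nose            = c( 1.00,  0.00),
    left_ear        = c( 0.62, -0.35),
    right_ear       = c( 0.62,  0.35),
    spine_front     = c( 0.45,  0.00),
    spine_mid       = c( 0.00,  0.00),
    spine_rear      = c(-0.45,  0.00),
    front_left_paw  = c( 0.35, -0.55),
    front_right_paw = c( 0.35,  0.55),
    back_left_paw   = c(-0.35, -0.55),
    back_right_paw  = c(-0.35,  0.55),
    tail_base       = c(-0.75,  0.00),
    tail_end        = c(-1.15,  0.00)
  )
  colnames(m) <- c("bx", "by")
  m
}

#' Describe a synthetic animal
#'
#' The body model is a parametric ellipse-blob layout: a pose parameter
#' vector (center, heading, scale) maps each named keypoint from a fixed
#' body frame into image coordinates. Each keypoint is rendered as a small
#' dot of keypoint-specific intensity with a dark surround, so that a small
#' convolutional network can learn to localize and identify it.
#'
#' @param keypoints Character vector of unique keypoint names, or `NULL`
#'   for the default 12-keypoint vocabulary (nose, two ears, three spine
#'   points, four paws, tail base/end).
#' @param image_size `c(height, width)` in pixels.
#' @param scale Mean body scale in pixels (distance nose to spine_mid).
#' @param body Optional matrix of body-frame coordinates (rows named by
#'   keypoint, columns bx, by). Required when `keypoints` is not a subset
#'   of the default vocabulary.
#' @return An object of class `animal_spec`.
#' @export
animal_spec <- function(keypoints = NULL, image_size = c(64, 64),
                        scale = 14, body = NULL) {
  body <- body %||% .default_body()
  keypoints <- keypoints %||% rownames(body)
  if (anyDuplicated(keypoints)) abort("keypoint names must be unique")
  missing <- setdiff(keypoints, rownames(body))
  if (length(missing) > 0) {
    abort(paste0("no body-model coordinates for: ",
                 paste(missing, collapse = ", ")))
  }
  stopifnot(length(image_size) == 2, all(image_size >= 16), scale > 0)
  structure(
    list(keypoints = keypoints,
         body = body[keypoints, , drop = FALSE],
         image_size = as.integer(image_size),
         scale = scale),
    class = "animal_spec"
  )
}

#' Describe a lab-specific annotation variant
#'
#' Emulates the heterogeneity of multi-lab pose data: each lab annotates a
#' subset of the canonical keypoints, may use its own names, and labels
#' with a systematic per-keypoint offset (annotator bias) plus random
#' noise (isotropic Gaussian, truncated at 3 SD).
#'
#' @param keypoint_subset Canonical names this lab annotates.
#' @param rename_map Named character vector `canonical -> lab-local` name;
#'   canonical names absent from it keep their names. Must be injective.
#' @param annotator_bias Named list/matrix of per-keypoint `c(dx, dy)`
#'   offsets in px (canonical names); unlisted keypoints get zero bias.
#' @param label_noise_sd Noise SD in px.
#' @return An object of class `lab_variant`.
#' @export
lab_variant <- function(keypoint_subset, rename_map = character(),
                        annotator_bias = list(), label_noise_sd = 0) {
  if (length(keypoint_subset) == 0) abort("keypoint_subset must be non-empty")
  if (anyDuplicated(keypoint_subset)) abort("keypoint_subset has duplicates")
  rename_map <- unlist(rename_map)
  if (length(rename_map) > 0) {
    if (is.null(names(rename_map)) || any(names(rename_map) == "")) {
      abort("rename_map must be a named vector (canonical -> local)")
    }
    if (anyDuplicated(rename_map)) abort("rename_map must be injective")
  }
  stopifnot(label_noise_sd >= 0)
  structure(
    list(keypoint_subset = keypoint_subset,
         rename_map = rename_map,
         annotator_bias = annotator_bias,
         label_noise_sd = label_noise_sd),
    class = "lab_variant"
  )
}

# Local (lab) name for canonical keypoints under a variant.
local_name <- function(variant, canonical) {
  out <- canonical
  hit <- canonical %in% names(variant$rename_map)
  out[hit] <- unname(variant$rename_map[canonical[hit]])
  out
}

#' Describe video motion
#'
#' @param kind One of `"linear"`, `"sinusoidal"`, `"random-walk"`.
#' @param speed Center speed in px/frame.
#' @param n_frames Number of frames (>= 2).
#' @param scale_drift Multiplicative body-scale factor applied each frame
#'   (1 = constant size).
#' @param heading Motion direction in radians (linear motion); default 0
#'   (rightward).
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(kind = c("linear", "sinusoidal", "random-walk"),
                        speed = 2, n_frames = 50, scale_drift = 1,
                        heading = 0) {
  kind <- match.arg(kind)
  if (n_frames < 2) abort("n_frames must be >= 2")
  stopifnot(speed >= 0, scale_drift > 0)
  structure(
    list(kind = kind, speed = speed, n_frames = as.integer(n_frames),
         scale_drift = scale_drift, heading = heading),
    class = "motion_spec"
  )
}

#' Describe a synthetic gait
#'
#' A cyclic quadruped gait: each hoof alternates stance (fixed on the
#' ground in world coordinates) and swing (advancing one stride length
#' while lifted). The body advances at constant speed
#' `stride_length / stride_period`. With `amplitude = 0` the gait
#' degenerates to rigid translation (hooves never step), which yields no
#' detectable events by construction.
#'
#' @param stride_period Full gait cycle length in frames (>= 4).
#' @param n_cycles Number of complete cycles inside the analysis window
#'   (>= 1).
#' @param amplitude Vertical hoof lift in px during swing.
#' @param duty_factor Fraction of the cycle in stance, strictly in (0, 1).
#' @param fps Frame rate in Hz.
#' @param stride_length Horizontal hoof displacement per cycle, px.
#' @param noise_sd Optional Gaussian jitter added to all coordinates, px.
#' @return An object of class `gait_spec`.
#' @export
gait_spec <- function(stride_period = 30, n_cycles = 5, amplitude = 6,
                      duty_factor = 0.6, fps = 30, stride_length = 120,
                      noise_sd = 0) {
  if (stride_period < 4) abort("stride_period < 4 frames is undetectable")
  if (n_cycles < 1) abort("n_cycles must be >= 1")
  if (duty_factor <= 0 || duty_factor >= 1) {
    abort("duty_factor must be strictly inside (0, 1)")
  }
  stopifnot(amplitude >= 0, fps > 0, stride_length > 0, noise_sd >= 0)
  structure(
    list(stride_period = as.integer(stride_period),
         n_cycles = as.integer(n_cycles),
         amplitude = amplitude, duty_factor = duty_factor, fps = fps,
         stride_length = stride_length, noise_sd = noise_sd),
    class = "gait_spec"
  )
}
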