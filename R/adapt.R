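# Memory-replay fine-tuning, pseudo-label video adaptation, the PPLO
# curriculum and constant-velocity Kalman baselines, and spatial-pyramid
# test-time inference.

#' Freeze model predictions as a pseudo-label store
#'
#' Pseudo labels are generated once from the incoming model and fixed
#' afterwards (no label drifting): the store records a content hash so
#' immutability can be asserted at any time.
#'
#' @param predictions Prediction tibble with `image_id`, `keypoint`, `x`,
#'   `y`, `confidence`.
#' @return List of class `pseudo_label_store`: `predictions`, `hash`.
#' @export
pseudo_label_store <- function(predictions) {
  predictions <- tibble::as_tibble(predictions)
  stopifnot(all(c("image_id", "keypoint", "x", "y", "confidence") %in%
                  names(predictions)))
  structure(list(predictions = predictions,
                 hash = rlang::hash(predictions)),
            class = "pseudo_label_store")
}

#' @rdname pseudo_label_store
#' @param model A trained `pose_model`.
#' @param images Named list of image matrices.
#' @export
generate_pseudo_labels <- function(model, images) {
  pseudo_label_store(predict(model, images))
}

#' @rdname pseudo_label_store
#' @param store A `pseudo_label_store`.
#' @export
store_hash <- function(store) {
  stopifnot(inherits(store, "pseudo_label_store"))
  rlang::hash(store$predictions)
}

#' Adaptation configuration
#'
#' @param threshold Confidence threshold in `[0, 1]` for accepting pseudo
#'   labels (0.7 for memory replay, 0.5 for video adaptation).
#' @param iterations Training iteration budget.
#' @param batch_size Images per step.
#' @param freeze_norm_stats Keep normalization running statistics fixed
#'   during adaptation (recommended).
#' @param seed RNG seed.
#' @param lr Learning rate.
#' @param loss A [loss_spec()].
#' @param peak_radius Target disk radius in map cells.
#' @return List of class `adapt_config`.
#' @export
adapt_config <- function(threshold = 0.5, iterations = 1000,
                         batch_size = 1, freeze_norm_stats = TRUE,
                         seed = 1, lr = 1e-4, loss = loss_spec(),
                         peak_radius = 1) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  stopifnot(iterations >= 1, batch_size >= 1)
  structure(list(threshold = threshold, iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 freeze_norm_stats = isTRUE(freeze_norm_stats), seed = seed,
                 lr = lr, loss = loss, peak_radius = peak_radius),
            class = "adapt_config")
}

as_train_config <- function(config) {
  train_config(steps = config$iterations, lr = config$lr,
               seed = config$seed, loss = config$loss,
               batch_size = config$batch_size,
               peak_radius = config$peak_radius,
               freeze_norm_stats = config$freeze_norm_stats)
}

#' Merge ground truth with confident pseudo labels
#'
#' For each super-set keypoint of one image: a flag >= 0 keeps the ground
#' truth; flag -1 with a pseudo-label confidence above the threshold
#' substitutes the pseudo coordinates (flag 2, trainable); otherwise the
#' keypoint stays masked. With threshold 1 no substitution ever happens
#' and memory replay degenerates to naive fine-tuning. The operation is
#' idempotent.
#'
#' @param gt Projected-annotation rows for one image (flags in
#'   {-1, 0, 1, 2}).
#' @param pseudo Prediction tibble for the same image (`keypoint`, `x`,
#'   `y`, `confidence`), or `NULL` (image trains with masks only).
#' @param threshold Confidence threshold.
#' @return Hybrid annotation tibble, same rows/order as `gt`.
#' @export
replay_merge <- function(gt, pseudo, threshold = 0.7) {
  stopifnot(all(gt$flag %in% -1:2))
  if (is.null(pseudo) || nrow(pseudo) == 0) return(gt)
  i <- match(gt$keypoint, pseudo$keypoint)
  conf <- ifelse(is.na(i), -Inf, pseudo$confidence[i])
  sub <- gt$flag == -1L & conf > threshold
  gt$x[sub] <- pseudo$x[i[sub]]
  gt$y[sub] <- pseudo$y[i[sub]]
  gt$flag[sub] <- 2L
  gt
}

#' Memory-replay fine-tuning
#'
#' Fine-tunes a model on a target dataset while substituting the model's
#' own frozen zero-shot predictions (the memory buffer) for keypoints the
#' target dataset does not define, preventing catastrophic forgetting of
#' the rest of the super-set vocabulary. The store must come from the
#' same pre-fine-tuning model.
#'
#' @param model A trained `pose_model`.
#' @param images Named list of image matrices.
#' @param annotations Projected-annotation tibble in the model's
#'   super-set vocabulary (flag -1 marks undefined keypoints).
#' @param store A [pseudo_label_store()] of zero-shot predictions.
#' @param config An [adapt_config()] (threshold 0.7 is the memory-replay
#'   default).
#' @return The fine-tuned `pose_model`.
#' @export
memory_replay_finetune <- function(model, images, annotations, store,
                                   config = adapt_config(threshold = 0.7)) {
  stopifnot(inherits(store, "pseudo_label_store"))
  vocab <- attr(annotations, "keypoints")
  ids <- unique(annotations$image_id)
  missing <- setdiff(ids, unique(store$predictions$image_id))
  if (length(missing) > 0) {
    warn(paste0("no pseudo labels for ", length(missing),
                " image(s); they train with masks only"))
  }
  hybrid <- annotations |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(function(g, key) {
      ps <- store$predictions[store$predictions$image_id ==
                                key$image_id[1], ]
      replay_merge(g, if (nrow(ps) > 0) ps else NULL,
                   threshold = config$threshold)
    }) |>
    dplyr::ungroup()
  attr(hybrid, "keypoints") <- vocab
  train_pose_model(model, images, hybrid, as_train_config(config))
}

#' Naive fine-tuning
#'
#' Plain masked-loss fine-tuning on the target annotations, with no
#' memory replay; weight-for-weight identical to
#' [memory_replay_finetune()] at threshold 1.
#'
#' @inheritParams memory_replay_finetune
#' @return The fine-tuned `pose_model`.
#' @export
naive_finetune <- function(model, images, annotations,
                           config = adapt_config(threshold = 1)) {
  train_pose_model(model, images, annotations, as_train_config(config))
}

#' Unsupervised video adaptation
#'
#' Runs zero-shot inference on the video once, freezes those predictions
#' as pseudo ground truth, masks low-confidence keypoints from the loss,
#' and fine-tunes the model on its own confident predictions (1000
#' iterations at batch size 1 by default, normalization running
#' statistics frozen).
#'
#' @param model A trained `pose_model`.
#' @param frames Named list of frame matrices (or a `pose_video`).
#' @param config An [adapt_config()].
#' @param store Optional precomputed [pseudo_label_store()]; generated
#'   from `model` when `NULL`.
#' @return The adapted `pose_model`.
#' @export
video_adapt <- function(model, frames, config = adapt_config(),
                        store = NULL) {
  if (inherits(frames, "pose_video")) frames <- video_frames(frames)
  store <- store %||% generate_pseudo_labels(model, frames)
  ann <- store$predictions |>
    dplyr::mutate(
      flag = ifelse(.data$confidence > config$threshold, 2L, -1L),
      x = ifelse(.data$flag == 2L, .data$x, 0),
      y = ifelse(.data$flag == 2L, .data$y, 0)) |>
    dplyr::select("image_id", "keypoint", "x", "y", "flag")
  if (all(ann$flag == -1L)) {
    abort(sprintf(
      "no pseudo label exceeds confidence %.2f on any frame; lower the threshold or inspect the model", config$threshold))
  }
  attr(ann, "keypoints") <- model$config$keypoints
  train_pose_model(model, frames, ann, as_train_config(config))
}

# Name video frames the way the frame-directory convention does.
video_frames <- function(video) {
  setNames(video$frames,
           sprintf("frame_%06d", seq_along(video$frames)))
}

#' Progressive pseudo-label optimization (PPLO) curriculum
#'
#' Easy-to-hard iterative pseudo-labeling: pseudo labels are regenerated
#' and trained on at each confidence level in sequence (default levels
#' 0.9, 0.7, 0.5 for four epochs each, 12 total epochs). A single level
#' is exactly [video_adapt()] at that threshold with the matched budget.
#'
#' @inheritParams video_adapt
#' @param levels Strictly decreasing confidence levels.
#' @param epochs_per_level Passes over the video per level.
#' @return The adapted `pose_model`, with a `pplo` element reporting the
#'   schedule (`total_epochs` etc.).
#' @export
pplo_adapt <- function(model, frames, levels = c(0.9, 0.7, 0.5),
                       epochs_per_level = 4, config = adapt_config()) {
  if (length(levels) == 0) abort("PPLO needs at least one confidence level")
  if (length(levels) > 1 && any(diff(levels) >= 0)) {
    abort("PPLO levels must be strictly decreasing")
  }
  if (inherits(frames, "pose_video")) frames <- video_frames(frames)
  n <- length(frames)
  for (lv in levels) {
    cfg <- config
    cfg$threshold <- lv
    cfg$iterations <- as.integer(epochs_per_level * n)
    model <- video_adapt(model, frames, cfg)
  }
  model$pplo <- list(levels = levels, epochs_per_level = epochs_per_level,
                     total_epochs = length(levels) * epochs_per_level)
  model
}

#' Constant-velocity Kalman smoothing of a pose track
#'
#' Forward constant-velocity Kalman filtering applied independently per
#' keypoint as post-processing (a baseline that modifies predictions, not
#' model weights). Frames with missing coordinates (NA) are handled by
#' prediction-only steps; confidences pass through unchanged.
#'
#' @param track Pose track tibble: `frame`, `keypoint`, `x`, `y`,
#'   optionally `confidence`.
#' @param process_var Process (acceleration) noise variance.
#' @param measurement_var Measurement noise variance.
#' @return Smoothed track tibble with the same columns.
#' @export
kalman_smooth <- function(track, process_var = 0.01,
                          measurement_var = 1) {
  assert_track(track)
  if (dplyr::n_distinct(track$frame) < 2) return(track)
  F1 <- matrix(c(1, 0, 1, 0,
                 0, 1, 0, 1,
                 0, 0, 1, 0,
                 0, 0, 0, 1), 4, 4, byrow = TRUE)  # state: x, y, vx, vy
  H <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0), 2, 4, byrow = TRUE)
  Q <- diag(c(0.25, 0.25, 1, 1)) * process_var
  R <- diag(2) * measurement_var
  track |>
    dplyr::group_by(.data$keypoint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      xs <- g$x; ys <- g$y
      ok1 <- which(is.finite(xs) & is.finite(ys))
      if (length(ok1) == 0) return(g)
      st <- c(xs[ok1[1]], ys[ok1[1]], 0, 0)
      P <- diag(c(100, 100, 100, 100))
      out_x <- xs; out_y <- ys
      for (i in seq_len(n)) {
        if (i > 1) {
          st <- F1 %*% st
          P <- F1 %*% P %*% t(F1) + Q
        }
        if (is.finite(xs[i]) && is.finite(ys[i])) {
          z <- c(xs[i], ys[i])
          S <- H %*% P %*% t(H) + R
          K <- P %*% t(H) %*% solve(S)
          st <- st + K %*% (z - H %*% st)
          P <- (diag(4) - K %*% H) %*% P
        }
        out_x[i] <- st[1]; out_y[i] <- st[2]
      }
      g$x <- out_x; g$y <- out_y
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame, .data$keypoint)
}

#' Spatial-pyramid configuration
#'
#' @param scales Rescaling targets: values > 8 are target heights in px,
#'   values <= 8 are scale factors relative to the input height. At least
#'   one scale.
#' @param confidence_threshold Scales whose mean keypoint confidence
#'   falls below this are discarded.
#' @param cosine_threshold Scales whose centered keypoint vector has a
#'   cosine similarity to the elementwise-median vector below this are
#'   discarded as outliers.
#' @return List of class `pyramid_config`.
#' @export
pyramid_config <- function(scales, confidence_threshold = 0.5,
                           cosine_threshold = 0.95) {
  if (length(scales) < 1) abort("at least one scale required")
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            cosine_threshold >= -1, cosine_threshold <= 1)
  structure(list(scales = scales,
                 confidence_threshold = confidence_threshold,
                 cosine_threshold = cosine_threshold),
            class = "pyramid_config")
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  sum(a * b) / (na * nb)
}

# Flatten predictions to a centered coordinate vector (translation
# invariant).
centered_vec <- function(preds) {
  v <- c(preds$x - mean(preds$x), preds$y - mean(preds$y))
  v
}

#' Spatial-pyramid test-time inference
#'
#' Runs inference at every pyramid scale, projects predictions back to
#' the original pixel space, drops scales with sub-threshold mean
#' confidence, drops outlier scales by cosine similarity of their
#' centered keypoint vector to the elementwise-median vector, and returns
#' the per-coordinate (lower) median of the surviving scales. If nothing
#' survives, the highest-confidence scale is returned with a warning.
#'
#' @param model A trained `pose_model`.
#' @param image Grayscale image matrix.
#' @param config A [pyramid_config()].
#' @return Prediction tibble `keypoint`, `x`, `y`, `confidence` in
#'   original image pixels.
#' @export
pyramid_infer <- function(model, image, config) {
  stopifnot(inherits(config, "pyramid_config"))
  H0 <- nrow(image); W0 <- ncol(image)
  heights <- vapply(config$scales, function(s)
    if (s <= 8) max(8L, as.integer(round(s * H0))) else as.integer(round(s)),
    integer(1))
  per_scale <- lapply(heights, function(h) {
    img <- resize_image(image, h)
    p <- infer_pose(model, img)
    p$x <- rescale_coords(p$x, ncol(img), W0)
    p$y <- rescale_coords(p$y, nrow(img), H0)
    p
  })
  if (length(per_scale) == 1) return(per_scale[[1]])
  conf <- vapply(per_scale, function(p) mean(p$confidence), numeric(1))
  surv <- which(conf >= config$confidence_threshold)
  if (length(surv) > 0) {
    med_vec <- apply(
      vapply(per_scale[surv], centered_vec,
             numeric(2 * nrow(per_scale[[1]]))), 1, lower_median)
    cs <- vapply(per_scale[surv], function(p)
      cosine_sim(centered_vec(p), med_vec), numeric(1))
    surv <- surv[cs >= config$cosine_threshold]
  }
  if (length(surv) == 0) {
    warn("no pyramid scale survived filtering; falling back to the highest-confidence scale")
    best <- order(-conf, heights)[1]
    return(per_scale[[best]])
  }
  agg <- per_scale[[surv[1]]]
  for (col in c("x", "y", "confidence")) {
    m <- vapply(per_scale[surv], function(p) p[[col]],
                numeric(nrow(agg)))
    agg[[col]] <- apply(matrix(m, nrow = nrow(agg)), 1, lower_median)
  }
  agg
}
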