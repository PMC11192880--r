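# Seeded generators for images, multi-lab annotation sets, videos and gait
# trajectories with known ground truth. Every downstream module's tests run
# on outputs of these generators.

# Map a pose parameter vector to image-space keypoints.
# pose: list(cx, cy, heading, scale). Returns tibble(keypoint, x, y).
pose_keypoints <- function(spec, pose) {
  b <- spec$body
  ct <- cos(pose$heading); st <- sin(pose$heading)
  x <- pose$cx + pose$scale * (b[, "bx"] * ct - b[, "by"] * st)
  y <- pose$cy + pose$scale * (b[, "bx"] * st + b[, "by"] * ct)
  tibble::tibble(keypoint = rownames(b), x = unname(x), y = unname(y))
}

# Render one grayscale image for a pose: ellipse body plus one dot of
# keypoint-specific intensity (with a dark surround ring) per keypoint.
# Feature sizes scale with the body, so rescaling an image changes the
# apparent feature size exactly as it would for a real animal.
render_pose_image <- function(spec, pose, noise_sd = 0.02) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  kp <- pose_keypoints(spec, pose)
  X <- matrix(rep(0:(w - 1), each = h), h, w)   # 0-based pixel centers
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  img <- matrix(0.15, h, w)
  # body ellipse in body frame
  ct <- cos(pose$heading); st <- sin(pose$heading)
  u <- ((X - pose$cx) * ct + (Y - pose$cy) * st) / pose$scale
  v <- (-(X - pose$cx) * st + (Y - pose$cy) * ct) / pose$scale
  img[(u / 1.25)^2 + (v / 0.62)^2 <= 1] <- 0.45
  # two-cue keypoint signature: 6 well-separated intensity shades crossed
  # with 2 dot sizes, so all 12 canonical keypoints stay distinguishable
  # under the label/pixel noise
  K <- nrow(kp)
  # every keypoint gets its own intensity shade; dot sizes alternate so
  # shade-adjacent keypoints also differ in size (two redundant cues)
  shades <- seq(0.60, 1.00, length.out = K)
  r_dot <- ifelse(seq_len(K) %% 2 == 1, 0.16, 0.28) * pose$scale
  r_ring <- 0.34 * pose$scale
  # all rings first, then all dots: a neighbouring keypoint's dark ring
  # must never overdraw another keypoint's dot
  d2 <- lapply(seq_len(K), function(i)
    (X - kp$x[i])^2 + (Y - kp$y[i])^2)
  for (i in seq_len(K)) img[d2[[i]] <= r_ring^2] <- 0.05
  for (i in seq_len(K)) img[d2[[i]] <= r_dot[i]^2] <- shades[i]
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
  }
  pmin(pmax(img, 0), 1)
}

# Sample a pose keeping the animal inside the frame when possible.
sample_pose <- function(spec, scale_jitter = 0.1) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  s <- spec$scale * runif(1, 1 - scale_jitter, 1 + scale_jitter)
  margin <- 1.35 * s
  cx <- if (w - 1 > 2 * margin) runif(1, margin, w - 1 - margin) else (w - 1) / 2
  cy <- if (h - 1 > 2 * margin) runif(1, margin, h - 1 - margin) else (h - 1) / 2
  list(cx = cx, cy = cy, heading = runif(1, 0, 2 * pi), scale = s)
}

in_frame <- function(x, y, image_size) {
  x >= 0 & x <= image_size[2] - 1 & y >= 0 & y <= image_size[1] - 1
}

#' Generate a synthetic annotated pose dataset
#'
#' Renders `n_images` single-animal images at random poses and annotates
#' them the way one "lab" would: only the variant's keypoint subset, under
#' the variant's local names, displaced by the variant's systematic
#' annotator bias plus truncated Gaussian label noise. The canonical
#' ground-truth coordinates are retained in a side channel for evaluation.
#' Identical `(spec, variant, seed)` give bit-identical output.
#'
#' @param spec An [animal_spec()].
#' @param n_images Number of images (>= 1).
#' @param variant A [lab_variant()]; defaults to the identity variant over
#'   the full canonical vocabulary.
#' @param seed Integer seed.
#' @param dataset_id Identifier recorded with every annotation.
#' @return A list of class `pose_dataset` with elements `images` (named
#'   list of H x W matrices), `annotations` (tibble: `dataset_id`,
#'   `image_id`, `keypoint` (local name), `x`, `y`, `flag` with COCO flags
#'   0/2), `truth` (tibble of canonical coordinates), `keypoints` (local
#'   vocabulary in canonical order), and the generating specs.
#' @export
generate_dataset <- function(spec, n_images, variant = NULL, seed = 1,
                             dataset_id = "lab") {
  stopifnot(inherits(spec, "animal_spec"), n_images >= 1)
  variant <- variant %||% lab_variant(spec$keypoints)
  bad <- setdiff(variant$keypoint_subset, spec$keypoints)
  if (length(bad) > 0) {
    abort(paste0("variant subset names absent from canonical vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  withr::with_seed(seed, {
    ids <- sprintf("%s_img_%04d", dataset_id, seq_len(n_images))
    images <- vector("list", n_images)
    names(images) <- ids
    truth <- vector("list", n_images)
    ann <- vector("list", n_images)
    subset <- variant$keypoint_subset
    for (i in seq_len(n_images)) {
      pose <- sample_pose(spec)
      images[[i]] <- render_pose_image(spec, pose)
      kp <- pose_keypoints(spec, pose)
      truth[[i]] <- tibble::tibble(image_id = ids[i], kp)
      tk <- kp[match(subset, kp$keypoint), ]
      vis <- in_frame(tk$x, tk$y, spec$image_size)
      nk <- length(subset)
      bias <- vapply(subset, function(nm) {
        b <- variant$annotator_bias[[nm]]
        if (is.null(b)) c(0, 0) else as.numeric(b)
      }, numeric(2))
      lx <- tk$x + bias[1, ] + trunc_norm(nk, variant$label_noise_sd)
      ly <- tk$y + bias[2, ] + trunc_norm(nk, variant$label_noise_sd)
      ann[[i]] <- tibble::tibble(
        dataset_id = dataset_id,
        image_id = ids[i],
        keypoint = local_name(variant, subset),
        x = ifelse(vis, lx, 0),
        y = ifelse(vis, ly, 0),
        flag = ifelse(vis, 2L, 0L)
      )
    }
    structure(
      list(images = images,
           annotations = dplyr::bind_rows(ann),
           truth = dplyr::bind_rows(truth),
           keypoints = local_name(variant, subset),
           canonical = subset,
           dataset_id = dataset_id,
           spec = spec, variant = variant, seed = seed),
      class = "pose_dataset"
    )
  })
}

#' @export
print.pose_dataset <- function(x, ...) {
  cat(sprintf("<pose_dataset '%s': %d images, %d keypoints (%s)>\n",
              x$dataset_id, length(x$images), length(x$keypoints),
              paste(utils::head(x$keypoints, 4), collapse = ", ")))
  invisible(x)
}

# Center trajectory for a motion spec; returns tibble(frame, cx, cy,
# heading, scale).
motion_path <- function(spec, motion, fps = 30) {
  n <- motion$n_frames
  h <- spec$image_size[1]; w <- spec$image_size[2]
  s0 <- spec$scale
  t <- 0:(n - 1)
  scale <- s0 * motion$scale_drift^t
  margin <- 1.35 * max(scale)
  mid <- c((w - 1) / 2, (h - 1) / 2)
  if (motion$kind == "linear") {
    dx <- cos(motion$heading) * motion$speed
    dy <- sin(motion$heading) * motion$speed
    # start so the path is as centered as possible
    cx <- mid[1] - dx * (n - 1) / 2 + dx * t
    cy <- mid[2] - dy * (n - 1) / 2 + dy * t
    heading <- rep(motion$heading, n)
  } else if (motion$kind == "sinusoidal") {
    period <- max(20, n / 2)
    amp <- 0.15 * h
    cx <- mid[1] - motion$speed * (n - 1) / 2 + motion$speed * t
    cy <- mid[2] + amp * sin(2 * pi * t / period)
    dy <- c(diff(cy), 0)
    dx <- rep(motion$speed, n)
    heading <- atan2(dy, dx)
  } else { # random-walk
    ang <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1, 0, 0.4)))
    step_x <- cos(ang) * motion$speed
    step_y <- sin(ang) * motion$speed
    cx <- mid[1] + cumsum(step_x) - mean(cumsum(step_x))
    cy <- mid[2] + cumsum(step_y) - mean(cumsum(step_y))
    heading <- ang
  }
  tibble::tibble(frame = seq_len(n), cx = cx, cy = cy,
                 heading = heading, scale = scale)
}

#' Generate a synthetic video with ground-truth track
#'
#' Renders a frame sequence for a moving animal and the per-frame
#' ground-truth keypoint track, aligned 1:1 with the frames. Frames in
#' which any keypoint leaves the image are flagged (attribute
#' `flagged_frames`), never silently dropped.
#'
#' @param spec An [animal_spec()].
#' @param motion A [motion_spec()].
#' @param seed Integer seed.
#' @param fps Frame rate recorded on the track (Hz).
#' @return A list of class `pose_video`: `frames` (list of matrices),
#'   `track` (tibble: frame, keypoint, x, y, confidence; attributes `fps`
#'   and `flagged_frames`), `path` (center trajectory), `spec`, `motion`.
#' @export
generate_video <- function(spec, motion, seed = 1, fps = 30) {
  stopifnot(inherits(spec, "animal_spec"), inherits(motion, "motion_spec"))
  withr::with_seed(seed, {
    path <- motion_path(spec, motion, fps)
    n <- nrow(path)
    frames <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      pose <- list(cx = path$cx[i], cy = path$cy[i],
                   heading = path$heading[i], scale = path$scale[i])
      frames[[i]] <- render_pose_image(spec, pose)
      kp <- pose_keypoints(spec, pose)
      rows[[i]] <- tibble::tibble(frame = i, kp, confidence = 1)
    }
    track <- dplyr::bind_rows(rows)
    out_of <- track |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(out = any(!in_frame(.data$x, .data$y, spec$image_size)))
    attr(track, "fps") <- fps
    attr(track, "flagged_frames") <- out_of$frame[out_of$out]
    structure(list(frames = frames, track = track, path = path,
                   spec = spec, motion = motion, seed = seed),
              class = "pose_video")
  })
}

#' @export
print.pose_video <- function(x, ...) {
  cat(sprintf("<pose_video: %d frames %dx%d, motion '%s'>\n",
              length(x$frames), x$spec$image_size[1], x$spec$image_size[2],
              x$motion$kind))
  invisible(x)
}

#' Generate a synthetic gait track with known events
#'
#' Produces a side-view quadruped walking track: four hooves alternating
#' stance (planted in world coordinates) and swing (advancing one stride
#' length on a smooth cosine profile while lifted by `amplitude`), a back
#' reference keypoint moving at constant speed, and a nose keypoint. Hoof
#' phases follow a four-beat walk (0, 0.5, 0.25, 0.75 cycles). The exact
#' touchdown (contact) and lift-off (lift) frames inside the analysis
#' window are returned for evaluation; the track is padded on both sides
#' with continued gait so that trimming `trim_seconds` leaves the
#' scheduled events intact, with `n_cycles` contacts and lifts per hoof.
#'
#' @param spec A [gait_spec()].
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param trim_seconds Lead-in/out padding the analysis is expected to
#'   discard (s); must match the trim used at detection time.
#' @return A list of class `gait_track`: `track` (tibble: frame, keypoint,
#'   x, y, confidence; attr `fps`), `events` (tibble: keypoint, event
#'   ("contact"/"lift"), frame), `window` (first/last analysed frame),
#'   `spec`.
#' @export
generate_gait_track <- function(spec, seed = 1, trim_seconds = 2) {
  stopifnot(inherits(spec, "gait_spec"))
  P <- spec$stride_period
  duty <- spec$duty_factor
  L <- spec$stride_length
  n_cyc <- spec$n_cycles
  trim_f <- round(trim_seconds * spec$fps)
  phases <- c(front_left_hoof = 0, front_right_hoof = 0.5,
              back_left_hoof = 0.75, back_right_hoof = 0.25)
  offsets <- c(front_left_hoof = 35, front_right_hoof = 35,
               back_left_hoof = -35, back_right_hoof = -35)

  # Align the analysis window inside the largest gap of the cyclic event
  # phase set so no scheduled event sits near a window edge.
  ev_phase <- sort(unique(round(c(phases, (phases + duty) %% 1), 9)))
  gaps <- diff(c(ev_phase, ev_phase[1] + 1))
  gi <- which.max(gaps)
  midgap <- ev_phase[gi] + gaps[gi] / 2
  delta <- gaps[gi] / 4
  t0 <- trim_f + (1 - (midgap %% 1)) * P      # schedule origin (0-based)
  b_end <- trim_f + (n_cyc + delta) * P
  n_frames <- ceiling(b_end) + trim_f
  window <- c(trim_f + 1L, as.integer(n_frames - trim_f))

  v <- L / P                                   # body speed px/frame
  tt <- 0:(n_frames - 1)
  x_body <- 50 + v * tt
  y_back <- 60
  y_ground <- 100

  hoof_xy <- function(phi, off) {
    if (spec$amplitude == 0) {                 # degenerate: rigid drag
      return(list(x = x_body + off, y = rep(y_ground, n_frames)))
    }
    tau <- (tt - t0) / P - phi
    cyc <- floor(tau)
    u <- tau - cyc
    x <- numeric(n_frames); y <- rep(y_ground, n_frames)
    stance <- u < duty
    x_contact <- 50 + off + (cyc + phi) * L + t0 * v
    x[stance] <- x_contact[stance]
    # linear swing advance: the hoof overtakes the body at constant
    # velocity, so the fore-aft position relative to the body peaks
    # exactly at touchdown and bottoms exactly at lift-off
    wsw <- (u[!stance] - duty) / (1 - duty)
    x[!stance] <- x_contact[!stance] + L * wsw
    y[!stance] <- y_ground - spec$amplitude * sin(pi * wsw)
    list(x = x, y = y)
  }

  rows <- list(tibble::tibble(frame = tt + 1L, keypoint = "back",
                              x = x_body, y = y_back, confidence = 1),
               tibble::tibble(frame = tt + 1L, keypoint = "nose",
                              x = x_body + 55, y = y_back - 5,
                              confidence = 1))
  events <- list()
  for (h in names(phases)) {
    xy <- hoof_xy(phases[[h]], offsets[[h]])
    rows[[h]] <- tibble::tibble(frame = tt + 1L, keypoint = h,
                                x = xy$x, y = xy$y, confidence = 1)
    if (spec$amplitude > 0) {
      cc <- -2:(n_cyc + 2)
      contact <- t0 + (cc + phases[[h]]) * P
      lift <- contact + duty * P
      keep_c <- contact > window[1] - 1 & contact <= window[2] - 1
      keep_l <- lift > window[1] - 1 & lift <= window[2] - 1
      events[[h]] <- dplyr::bind_rows(
        tibble::tibble(keypoint = h, event = "contact",
                       frame = as.integer(round(contact[keep_c])) + 1L),
        tibble::tibble(keypoint = h, event = "lift",
                       frame = as.integer(round(lift[keep_l])) + 1L)
      )
    }
  }
  track <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$frame, .data$keypoint)
  if (spec$noise_sd > 0) {
    track <- withr::with_seed(seed, {
      track$x <- track$x + rnorm(nrow(track), 0, spec$noise_sd)
      track$y <- track$y + rnorm(nrow(track), 0, spec$noise_sd)
      track
    })
  }
  attr(track, "fps") <- spec$fps
  ev <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(keypoint = character(), event = character(),
                   frame = integer())
  structure(list(track = track, events = ev, window = window, spec = spec,
                 seed = seed),
            class = "gait_track")
}

#' @export
print.gait_track <- function(x, ...) {
  cat(sprintf(
    "<gait_track: %d frames @ %g fps, %d cycles, %d ground-truth events>\n",
    max(x$track$frame), x$spec$fps, x$spec$n_cycles, nrow(x$events)))
  invisible(x)
}
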