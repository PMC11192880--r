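# Downstream behavioral computation: skeleton features and windowed action
# classification, plus gait-event detection with stride/stance statistics.

#' Skeleton feature specification
#'
#' A 22-dimensional per-frame feature vector: 10 keypoint-pair distances,
#' 6 interior angles, 4 polygon areas, and 2 region-membership booleans
#' (nose-in-arena and head-center-in-arena against an externally supplied
#' arena polygon). The identities are fully configurable; the default set
#' is an anatomically sensible choice over the package's canonical
#' 12-keypoint vocabulary.
#'
#' @param distances List of exactly 10 keypoint-name pairs.
#' @param angles List of exactly 6 keypoint-name triplets (angle at the
#'   middle name).
#' @param areas List of exactly 4 keypoint-name sets (>= 3 names each,
#'   polygon in the given order).
#' @param nose_keypoint,head_keypoint Names used for the two region
#'   booleans.
#' @param arena Two-column matrix of arena-polygon corners (px).
#' @return List of class `feature_spec` (total dimension 22).
#' @export
feature_spec <- function(distances = NULL, angles = NULL, areas = NULL,
                         nose_keypoint = "nose",
                         head_keypoint = "spine_front",
                         arena = cbind(c(0, 63, 63, 0), c(0, 0, 63, 63))) {
  distances <- distances %||% list(
    c("nose", "tail_base"), c("nose", "spine_mid"),
    c("left_ear", "right_ear"), c("spine_front", "spine_rear"),
    c("front_left_paw", "front_right_paw"),
    c("back_left_paw", "back_right_paw"),
    c("front_left_paw", "back_left_paw"),
    c("front_right_paw", "back_right_paw"),
    c("spine_mid", "tail_base"), c("tail_base", "tail_end"))
  angles <- angles %||% list(
    c("nose", "spine_front", "spine_mid"),
    c("spine_front", "spine_mid", "spine_rear"),
    c("spine_mid", "spine_rear", "tail_base"),
    c("spine_rear", "tail_base", "tail_end"),
    c("left_ear", "nose", "right_ear"),
    c("front_left_paw", "spine_mid", "front_right_paw"))
  areas <- areas %||% list(
    c("nose", "left_ear", "right_ear"),
    c("spine_front", "front_right_paw", "spine_mid", "front_left_paw"),
    c("spine_mid", "back_right_paw", "tail_base", "back_left_paw"),
    c("nose", "right_ear", "front_right_paw", "back_right_paw",
      "tail_base", "back_left_paw", "front_left_paw", "left_ear"))
  if (length(distances) != 10) abort("feature_spec needs exactly 10 distances")
  if (length(angles) != 6) abort("feature_spec needs exactly 6 angles")
  if (length(areas) != 4) abort("feature_spec needs exactly 4 areas")
  stopifnot(is.matrix(arena), ncol(arena) == 2, nrow(arena) >= 3)
  structure(list(distances = distances, angles = angles, areas = areas,
                 nose_keypoint = nose_keypoint,
                 head_keypoint = head_keypoint, arena = arena,
                 dimension = 22L),
            class = "feature_spec")
}

interior_angle <- function(ax, ay, bx, by, cx, cy) {
  v1x <- ax - bx; v1y <- ay - by
  v2x <- cx - bx; v2y <- cy - by
  dot <- v1x * v2x + v1y * v2y
  nn <- sqrt(v1x^2 + v1y^2) * sqrt(v2x^2 + v2y^2)
  acos(pmin(pmax(dot / pmax(nn, 1e-12), -1), 1))
}

#' Per-frame skeleton features
#'
#' Computes the 22-D feature series for a pose track: distances in px,
#' interior angles in radians, polygon areas in px^2, and 0/1 region
#' booleans via point-in-polygon against the arena.
#'
#' @param track Pose track tibble: `frame`, `keypoint`, `x`, `y`.
#' @param spec A [feature_spec()].
#' @return Tibble: `frame` plus 22 feature columns.
#' @export
skeleton_features <- function(track, spec = feature_spec()) {
  assert_track(track)
  need <- unique(c(unlist(spec$distances), unlist(spec$angles),
                   unlist(spec$areas), spec$nose_keypoint,
                   spec$head_keypoint))
  missing <- setdiff(need, unique(track$keypoint))
  if (length(missing) > 0) {
    abort(paste0("keypoint(s) referenced by the feature spec are missing ",
                 "from the track: ", paste(missing, collapse = ", ")))
  }
  wide <- track |>
    dplyr::select("frame", "keypoint", "x", "y") |>
    tidyr::pivot_wider(names_from = "keypoint",
                       values_from = c("x", "y"))
  gx <- function(nm) wide[[paste0("x_", nm)]]
  gy <- function(nm) wide[[paste0("y_", nm)]]
  out <- tibble::tibble(frame = wide$frame)
  for (i in seq_along(spec$distances)) {
    p <- spec$distances[[i]]
    out[[paste0("dist_", p[1], "_", p[2])]] <-
      sqrt((gx(p[1]) - gx(p[2]))^2 + (gy(p[1]) - gy(p[2]))^2)
  }
  for (i in seq_along(spec$angles)) {
    a <- spec$angles[[i]]
    out[[paste0("angle_", a[2], "_", i)]] <-
      interior_angle(gx(a[1]), gy(a[1]), gx(a[2]), gy(a[2]),
                     gx(a[3]), gy(a[3]))
  }
  for (i in seq_along(spec$areas)) {
    s <- spec$areas[[i]]
    xm <- sapply(s, gx); ym <- sapply(s, gy)
    out[[paste0("area_", i)]] <- vapply(seq_len(nrow(wide)), function(r)
      shoelace_area(xm[r, ], ym[r, ]), numeric(1))
  }
  bnd <- rbind(spec$arena, spec$arena[1, ])
  out$nose_in_arena <- as.numeric(
    mgcv::in.out(bnd, cbind(gx(spec$nose_keypoint),
                            gy(spec$nose_keypoint))))
  out$head_in_arena <- as.numeric(
    mgcv::in.out(bnd, cbind(gx(spec$head_keypoint),
                            gy(spec$head_keypoint))))
  out
}

f1_score <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Sliding-window action classification with leave-one-video-out folds
#'
#' A one-hidden-layer feed-forward classifier consumes the flattened
#' feature window centered on each frame (31 time steps by default) and
#' predicts the frame's action label. Folds leave one video out; the
#' per-class F1 score is reported per fold and aggregated.
#'
#' @param features Tibble with `video_id`, `frame`, `label` and numeric
#'   feature columns (e.g., from [skeleton_features()]).
#' @param window Odd window length in frames.
#' @param hidden Hidden-layer width.
#' @param decay Weight decay (regularization in place of early stopping).
#' @param maxit Optimizer iteration cap.
#' @param seed Seed controlling weight initialization per fold.
#' @return List of class `action_classifier_result`: `per_fold` tibble
#'   (video_id, class, f1), `f1` tibble (class, mean f1), `window`.
#' @export
window_classify <- function(features, window = 31, hidden = 128,
                            decay = 1e-3, maxit = 150, seed = 1) {
  stopifnot(all(c("video_id", "frame", "label") %in% names(features)))
  if (window %% 2 != 1) abort("window must be odd")
  vids <- unique(features$video_id)
  if (length(vids) < 2) abort("leave-one-video-out needs >= 2 videos")
  feat_cols <- setdiff(names(features), c("video_id", "frame", "label"))
  half <- (window - 1) / 2

  build <- function(df) {
    df <- dplyr::arrange(df, .data$frame)
    n <- nrow(df)
    if (n < window) {
      abort("window longer than the shortest video")
    }
    centers <- (half + 1):(n - half)
    X <- matrix(0, length(centers), length(feat_cols) * window)
    fm <- as.matrix(df[, feat_cols])
    for (j in seq_len(window)) {
      X[, ((j - 1) * length(feat_cols) + 1):(j * length(feat_cols))] <-
        fm[centers - half + (j - 1), , drop = FALSE]
    }
    list(X = X, y = df$label[centers])
  }
  sets <- lapply(vids, function(v) build(features[features$video_id == v, ]))
  names(sets) <- vids
  classes <- sort(unique(as.character(features$label)))

  per_fold <- purrr::map_dfr(seq_along(vids), function(k) {
    tr <- sets[-k]
    Xtr <- do.call(rbind, lapply(tr, `[[`, "X"))
    ytr <- factor(unlist(lapply(tr, `[[`, "y")), levels = classes)
    mu <- colMeans(Xtr)
    sd_ <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
    Xte <- sweep(sweep(sets[[k]]$X, 2, mu), 2, sd_, "/")
    yte <- factor(sets[[k]]$y, levels = classes)
    fit <- withr::with_seed(seed + k, {
      nnet::nnet(Xtr, nnet::class.ind(ytr), size = hidden, decay = decay,
                 maxit = maxit, softmax = length(classes) > 2,
                 entropy = length(classes) <= 2,
                 MaxNWts = 1e7, trace = FALSE)
    })
    pr <- predict(fit, Xte)
    pred <- if (ncol(as.matrix(pr)) > 1) {
      classes[max.col(pr, ties.method = "first")]
    } else {
      classes[(pr[, 1] > 0.5) + 1]
    }
    tibble::tibble(video_id = vids[k],
                   class = classes,
                   f1 = vapply(classes, function(cl)
                     f1_score(as.character(yte), pred, cl), numeric(1)))
  })
  f1 <- per_fold |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(f1 = mean(.data$f1, na.rm = TRUE))
  structure(list(per_fold = per_fold, f1 = f1, window = window),
            class = "action_classifier_result")
}

#' @export
print.action_classifier_result <- function(x, ...) {
  cat(sprintf("<action_classifier_result: window %d, %d folds>\n",
              x$window, dplyr::n_distinct(x$per_fold$video_id)))
  print(x$f1)
  invisible(x)
}

#' Zero-lag Butterworth filtering of a pose track
#'
#' Forward-backward (zero-phase) low-pass Butterworth filtering applied
#' per keypoint and coordinate.
#'
#' @param track Pose track tibble.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order.
#' @param fps Frame rate (Hz); default from `attr(track, "fps")`.
#' @return Filtered track, same shape; attributes preserved.
#' @export
filter_track <- function(track, cutoff = 3, order = 2, fps = NULL) {
  assert_track(track)
  fps <- track_fps(track, fps)
  if (cutoff >= fps / 2) {
    abort(sprintf("cutoff %g Hz is at or above the Nyquist frequency %g Hz",
                  cutoff, fps / 2))
  }
  nmin <- 3 * (order + 1)
  bf <- signal::butter(order, cutoff / (fps / 2), type = "low")
  # forward-backward filtering with odd-reflection padding so edge
  # transients (the filter starts from rest) stay out of the signal
  zl_filter <- function(x) {
    n <- length(x)
    np <- min(n - 1, ceiling(3 * fps / cutoff))
    pre <- 2 * x[1] - x[seq(np + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - np)]
    xp <- c(pre, x, post)
    y <- as.numeric(signal::filtfilt(bf, xp))
    y[(np + 1):(np + n)]
  }
  out <- track |>
    dplyr::group_by(.data$keypoint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) <= nmin) {
        abort("track shorter than the filter warm-up")
      }
      g$x <- zl_filter(g$x)
      g$y <- zl_filter(g$y)
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame, .data$keypoint)
  attr(out, "fps") <- fps
  out
}

# Enforce alternation: among adjacent same-type events keep the more
# extreme one (largest |value| relative to the trace).
enforce_alternation <- function(ev, values) {
  if (nrow(ev) <= 1) return(ev)
  ev <- dplyr::arrange(ev, .data$frame)
  keep <- rep(TRUE, nrow(ev))
  i <- 1
  while (i < nrow(ev)) {
    j <- i + 1
    while (j <= nrow(ev) && !keep[j]) j <- j + 1
    if (j > nrow(ev)) break
    if (ev$event[i] == ev$event[j]) {
      vi <- values[ev$frame[i]]; vj <- values[ev$frame[j]]
      better_j <- if (ev$event[i] == "contact") vj > vi else vj < vi
      if (better_j) keep[i] <- FALSE else keep[j] <- FALSE
      if (better_j) i <- j
    } else {
      i <- j
    }
  }
  ev[keep, ]
}

#' Detect gait events from a pose track
#'
#' Hoof trajectories are low-pass filtered (zero-lag Butterworth),
#' re-expressed relative to a keypoint on the animal's back (a reference
#' frame stationary relative to the moving animal), and trimmed at both
#' ends. Ground contacts are detected as peaks of the fore-aft relative
#' position (the hoof is most anterior at touchdown) and lift-offs as its
#' valleys (most posterior at lift); alternation is enforced by keeping
#' the more extreme of adjacent same-type events.
#'
#' @param track Pose track tibble including hoof and back keypoints.
#' @param back_keypoint Name of the back reference keypoint.
#' @param hooves Hoof keypoint names; default: every keypoint whose name
#'   contains "hoof".
#' @param trim_seconds Seconds discarded at each end.
#' @param cutoff,order Butterworth parameters (3 Hz, 2nd order).
#' @param fps Frame rate; default from the track attribute.
#' @return Tibble of class `gait_events`: `keypoint`, `event`
#'   ("contact"/"lift"), `frame`; attribute `window`.
#' @export
detect_gait_events <- function(track, back_keypoint = "back",
                               hooves = NULL, trim_seconds = 2,
                               cutoff = 3, order = 2, fps = NULL) {
  assert_track(track)
  fps <- track_fps(track, fps)
  hooves <- hooves %||% grep("hoof", unique(track$keypoint), value = TRUE)
  if (!back_keypoint %in% track$keypoint) {
    abort(sprintf("back keypoint '%s' absent from track", back_keypoint))
  }
  if (length(hooves) == 0) abort("no hoof keypoints found")
  filt <- filter_track(track[track$keypoint %in% c(back_keypoint, hooves), ],
                       cutoff = cutoff, order = order, fps = fps)
  frames <- sort(unique(filt$frame))
  trim_f <- round(trim_seconds * fps)
  lo <- frames[1] + trim_f
  hi <- frames[length(frames)] - trim_f
  if (lo >= hi) abort("track too short for the requested trim")
  back_x <- filt$x[filt$keypoint == back_keypoint]
  ev <- purrr::map_dfr(hooves, function(h) {
    hx <- filt$x[filt$keypoint == h]
    rel <- hx - back_x
    win <- frames >= lo & frames <= hi
    rel_w <- rel[win]
    fr_w <- frames[win]
    rng <- diff(range(rel_w))
    if (!is.finite(rng) || rng < 1e-6) {
      return(tibble::tibble(keypoint = character(), event = character(),
                            frame = integer()))
    }
    find_ev <- function(v, type) {
      pk <- pracma::findpeaks(v, minpeakheight = mean(v) +
                                0.25 * (max(v) - mean(v)),
                              minpeakdistance = 3)
      if (is.null(pk)) return(NULL)
      tibble::tibble(keypoint = h, event = type,
                     frame = as.integer(fr_w[pk[, 2]]))
    }
    out <- dplyr::bind_rows(find_ev(rel_w, "contact"),
                            find_ev(-rel_w, "lift"))
    if (nrow(out) == 0) return(out)
    vals <- setNames(rel_w, fr_w)
    values <- rep(NA_real_, max(fr_w))
    values[fr_w] <- rel_w
    enforce_alternation(out, values)
  })
  ev <- dplyr::arrange(ev, .data$keypoint, .data$frame)
  attr(ev, "window") <- c(lo, hi)
  attr(ev, "fps") <- fps
  class(ev) <- c("gait_events", class(ev))
  ev
}

#' Stride and stance statistics from gait events
#'
#' Stride length is the world-frame horizontal hoof displacement between
#' consecutive ground contacts; stance duration spans a contact until the
#' same hoof's next lift. Unpaired events are skipped with a warning.
#'
#' @param events `gait_events` tibble (or the `events` element of a
#'   [generate_gait_track()] result).
#' @param track The (unfiltered) pose track the events refer to.
#' @return List of class `stride_stats`: `strides` (keypoint,
#'   start_frame, end_frame, length_px), `stances` (keypoint, contact,
#'   lift, duration_frames), `contacts` (keypoint, n_contacts).
#' @export
stride_stats <- function(events, track) {
  assert_track(track)
  hooves <- unique(events$keypoint)
  strides <- list(); stances <- list(); contacts <- list()
  skipped <- 0L
  for (h in hooves) {
    e <- events[events$keypoint == h, ]
    cts <- sort(e$frame[e$event == "contact"])
    lfs <- sort(e$frame[e$event == "lift"])
    hx <- track$x[track$keypoint == h]
    hf <- track$frame[track$keypoint == h]
    contacts[[h]] <- tibble::tibble(keypoint = h,
                                    n_contacts = length(cts))
    if (length(cts) >= 2) {
      strides[[h]] <- tibble::tibble(
        keypoint = h,
        start_frame = cts[-length(cts)],
        end_frame = cts[-1],
        length_px = abs(hx[match(cts[-1], hf)] -
                          hx[match(cts[-length(cts)], hf)]))
    }
    st <- lapply(cts, function(ct) {
      nxt <- lfs[lfs > ct]
      if (length(nxt) == 0) return(NULL)
      tibble::tibble(keypoint = h, contact = ct, lift = nxt[1],
                     duration_frames = nxt[1] - ct)
    })
    skipped <- skipped + sum(vapply(st, is.null, logical(1)))
    stances[[h]] <- dplyr::bind_rows(st)
  }
  if (skipped > 0) {
    warn(sprintf("%d contact(s) without a following lift were skipped",
                 skipped))
  }
  structure(list(strides = dplyr::bind_rows(strides),
                 stances = dplyr::bind_rows(stances),
                 contacts = dplyr::bind_rows(contacts)),
            class = "stride_stats")
}

#' @export
print.stride_stats <- function(x, ...) {
  cat(sprintf(
    "<stride_stats: %d strides (mean %.1f px), %d stances (mean %.1f frames)>\n",
    nrow(x$strides), mean(x$strides$length_px),
    nrow(x$stances), mean(x$stances$duration_frames)))
  invisible(x)
}
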