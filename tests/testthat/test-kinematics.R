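# Synthetic behavior fixture: random-walk videos in which "rear" episodes
# contract the body toward its centroid, making labels a deterministic
# function of body geometry.
behavior_features <- function(n_videos = 3, n_frames = 100) {
  fixture(sprintf("behavior_%d_%d", n_videos, n_frames), function() {
    spec <- animal_spec(image_size = c(96, 96))
    mk <- function(seed) {
      v <- generate_video(spec, motion_spec("random-walk", speed = 1,
                                            n_frames = n_frames),
                          seed = seed)
      withr::with_seed(seed + 100, {
        ep <- sort(sample(20:(n_frames - 20), 3))
        lab <- rep("move", n_frames)
        for (e in ep) lab[e:(e + 8)] <- "rear"
      })
      tr <- v$track |>
        dplyr::group_by(frame) |>
        dplyr::mutate(
          x = if (lab[frame[1]] == "rear")
            mean(x) + 0.45 * (x - mean(x)) else x,
          y = if (lab[frame[1]] == "rear")
            mean(y) + 0.45 * (y - mean(y)) else y) |>
        dplyr::ungroup()
      f <- skeleton_features(
        tr, feature_spec(arena = cbind(c(0, 95, 95, 0),
                                       c(0, 0, 95, 95))))
      dplyr::mutate(f, video_id = paste0("v", seed),
                    label = lab[f$frame])
    }
    dplyr::bind_rows(lapply(seq_len(n_videos), mk))
  })
}

test_that("skeleton features are 22-dimensional with correct geometry", {
  spec <- animal_spec()
  v <- generate_video(spec, motion_spec(n_frames = 6), seed = 2)
  f <- skeleton_features(v$track, feature_spec())
  expect_equal(ncol(f) - 1, 22)
  # collinear triplet has interior angle pi
  tr <- tidyr::expand_grid(frame = 1:2,
                           keypoint = c("a", "b", "c")) |>
    dplyr::mutate(x = rep(c(0, 1, 2), 2), y = 0)
  expect_equal(interior_angle(0, 0, 1, 0, 2, 0), pi)
  expect_equal(interior_angle(1, 0, 0, 0, 0, 1), pi / 2)
})

test_that("region booleans follow point-in-polygon against the arena", {
  spec <- animal_spec()
  arena <- cbind(c(20, 44, 44, 20), c(20, 20, 44, 44))
  tr <- tidyr::expand_grid(frame = 1:2, keypoint = spec$keypoints) |>
    dplyr::mutate(x = 32, y = 32)
  tr$x[tr$frame == 2 & tr$keypoint == "nose"] <- 60
  tr$y[tr$frame == 2 & tr$keypoint == "nose"] <- 60
  f <- skeleton_features(tr, feature_spec(arena = arena))
  expect_equal(f$nose_in_arena, c(1, 0))
  expect_equal(f$head_in_arena, c(1, 1))
})

test_that("missing feature keypoints are reported by name", {
  tr <- tibble::tibble(frame = 1, keypoint = "nose", x = 1, y = 1)
  expect_error(skeleton_features(tr, feature_spec()), "tail_base")
})

test_that("zero-lag Butterworth filtering has the stated frequency response", {
  fps <- 100
  n <- 1000
  t <- (0:(n - 1)) / fps
  sig <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 20 * t)
  tr <- tibble::tibble(frame = 1:n, keypoint = "k", x = sig, y = 0)
  attr(tr, "fps") <- fps
  out <- filter_track(tr, cutoff = 3, order = 2)
  amp <- function(x, f) {
    sp <- Mod(stats::fft(x))[f * n / fps + 1] * 2 / n
    sp
  }
  expect_gt(amp(out$x, 0.5), 0.95)   # passband essentially preserved
  expect_lt(amp(out$x, 20), 0.1)     # stopband down by > 20 dB
  # constant signal passes through unchanged
  cst <- dplyr::mutate(tr, x = 3.5)
  attr(cst, "fps") <- fps
  expect_equal(filter_track(cst, 3)$x, rep(3.5, n), tolerance = 1e-8)
  # symmetric pulse stays symmetric about its center (zero lag)
  pulse <- dplyr::mutate(tr, x = exp(-((frame - 500)^2) / 200))
  attr(pulse, "fps") <- fps
  fx <- filter_track(pulse, 3)$x
  expect_equal(fx[450:499], rev(fx[501:550]), tolerance = 1e-6)
  expect_error(filter_track(tr, cutoff = 60), "Nyquist")
})

test_that("gait events are recovered exactly from noise-free fixtures", {
  g <- generate_gait_track(gait_spec())
  ev <- detect_gait_events(g$track)
  got <- tibble::as_tibble(dplyr::count(tibble::as_tibble(ev),
                                        keypoint, event))
  want <- dplyr::count(g$events, keypoint, event)
  expect_equal(dplyr::arrange(got, keypoint, event),
               dplyr::arrange(want, keypoint, event),
               ignore_attr = TRUE)
  j <- dplyr::inner_join(g$events, ev, by = c("keypoint", "event"),
                         relationship = "many-to-many") |>
    dplyr::group_by(keypoint, event, frame.x) |>
    dplyr::summarise(err = min(abs(frame.x - frame.y)),
                     .groups = "drop")
  expect_lte(max(j$err), 1)
})

test_that("gait events survive small label noise within one frame", {
  g <- generate_gait_track(gait_spec(noise_sd = 0.5), seed = 8)
  ev <- detect_gait_events(g$track)
  expect_equal(nrow(ev), nrow(g$events))
  j <- dplyr::inner_join(g$events, ev, by = c("keypoint", "event"),
                         relationship = "many-to-many") |>
    dplyr::group_by(keypoint, event, frame.x) |>
    dplyr::summarise(err = min(abs(frame.x - frame.y)),
                     .groups = "drop")
  expect_lte(max(j$err), 1)
})

test_that("whole-body drift does not move gait events (centering)", {
  g <- generate_gait_track(gait_spec())
  ev0 <- detect_gait_events(g$track)
  drifted <- dplyr::mutate(g$track, x = x + 3 * frame)
  attr(drifted, "fps") <- attr(g$track, "fps")
  ev1 <- detect_gait_events(drifted)
  expect_equal(tibble::as_tibble(ev0), tibble::as_tibble(ev1))
})

test_that("amplitude-0 gaits yield no events without error", {
  g0 <- generate_gait_track(gait_spec(amplitude = 0))
  ev <- detect_gait_events(g0$track)
  expect_equal(nrow(ev), 0)
})

test_that("stride and stance statistics match generator truth", {
  g <- generate_gait_track(gait_spec(n_cycles = 5, duty_factor = 0.6,
                                     stride_period = 30))
  ev <- detect_gait_events(g$track)
  st <- suppressWarnings(stride_stats(ev, g$track))
  # 5 contacts -> 4 strides per hoof
  expect_equal(nrow(st$strides), 4 * 4)
  expect_true(all(abs(st$strides$length_px - 120) / 120 < 0.02))
  expect_true(all(abs(st$stances$duration_frames - 18) <= 1))
  expect_equal(sum(st$contacts$n_contacts), 20)
  expect_equal(glance(st)$n_strides, 16)
})

test_that("windowed classification separates geometry-determined labels", {
  feats <- behavior_features()
  res <- window_classify(feats, window = 31, hidden = 4, maxit = 150,
                         seed = 2)
  expect_true(all(res$f1$f1 > 0.9))
  res_again <- window_classify(feats, window = 31, hidden = 4,
                               maxit = 150, seed = 2)
  expect_identical(res$f1, res_again$f1)
  expect_equal(glance(res)$window, 31)
})

test_that("label-shuffled controls collapse toward chance", {
  feats <- behavior_features()
  shuf <- feats
  withr::with_seed(1, shuf$label <- sample(shuf$label))
  res <- window_classify(shuf, window = 31, hidden = 4, maxit = 150,
                         seed = 2)
  prev <- mean(feats$label == "rear")
  f1_rear <- res$f1$f1[res$f1$class == "rear"]
  expect_lt(f1_rear, 0.6)
  expect_lt(abs(f1_rear - prev), 0.3)
})

test_that("windows longer than the shortest video are rejected", {
  feats <- behavior_features()
  short <- dplyr::filter(feats, frame <= 20 | video_id != "v1")
  expect_error(window_classify(short, window = 31, hidden = 2,
                               maxit = 10),
               "window longer")
})
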