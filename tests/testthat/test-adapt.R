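test_that("replay_merge follows the substitution rule table", {
  gt <- tibble::tibble(keypoint = c("a", "b", "c", "d"),
                       x = c(1, 2, 0, 0), y = c(1, 2, 0, 0),
                       flag = c(2L, 0L, -1L, -1L))
  pseudo <- tibble::tibble(keypoint = c("a", "b", "c", "d"),
                           x = 10:13, y = 20:23,
                           confidence = c(0.9, 0.9, 0.8, 0.6))
  h <- replay_merge(gt, pseudo, threshold = 0.7)
  # flags >= 0 keep ground truth
  expect_equal(h$x[1:2], c(1, 2))
  expect_equal(h$flag[1:2], c(2L, 0L))
  # -1 with confidence 0.8 > 0.7 substitutes; 0.6 stays masked
  expect_equal(h$flag[3], 2L)
  expect_equal(h$x[3], 12)
  expect_equal(h$flag[4], -1L)
  # idempotent
  expect_identical(replay_merge(h, pseudo, 0.7), h)
  # threshold 1: no substitution ever
  expect_identical(replay_merge(gt, pseudo, 1), gt)
  # all flags >= 0: unchanged
  gt2 <- dplyr::mutate(gt, flag = 2L)
  expect_identical(replay_merge(gt2, pseudo, 0.7), gt2)
  # missing pseudo entries leave the keypoint masked
  expect_identical(replay_merge(gt, NULL, 0.7), gt)
})

test_that("pseudo-label stores are frozen (hash-stable through training)", {
  q <- quick_model()
  store <- generate_pseudo_labels(q$model, q$ds$images[1:4])
  h0 <- store_hash(store)
  invisible(memory_replay_finetune(
    q$model, q$ds$images[1:4],
    dplyr::filter(q$proj, image_id %in% names(q$ds$images)[1:4]) |>
      structure(keypoints = attr(q$proj, "keypoints")),
    store, adapt_config(threshold = 0.7, iterations = 15, seed = 2)))
  expect_identical(store_hash(store), h0)
  expect_identical(h0, store$hash)
})

test_that("threshold-1 memory replay equals naive fine-tuning weight-for-weight", {
  q <- quick_model()
  sub_ids <- names(q$ds$images)[1:5]
  ann <- dplyr::filter(q$proj, image_id %in% sub_ids)
  attr(ann, "keypoints") <- attr(q$proj, "keypoints")
  store <- generate_pseudo_labels(q$model, q$ds$images[sub_ids])
  cfg <- adapt_config(threshold = 1, iterations = 40, seed = 9,
                      lr = 1e-3, freeze_norm_stats = FALSE)
  m_replay <- memory_replay_finetune(q$model, q$ds$images[sub_ids], ann,
                                     store, cfg)
  m_naive <- naive_finetune(q$model, q$ds$images[sub_ids], ann, cfg)
  expect_identical(m_replay$params, m_naive$params)
  expect_identical(m_replay$running, m_naive$running)
})

test_that("video adaptation validates pseudo labels and reproduces per seed", {
  q <- quick_model()
  vid <- generate_video(animal_spec(), motion_spec(n_frames = 6),
                        seed = 41)
  frames <- frames_named(vid)
  # an untrained model is everywhere under-confident: abort
  fresh <- toy_pose_model(q$superset, channels = 8, seed = 1)
  expect_error(video_adapt(fresh, frames,
                           adapt_config(threshold = 0.5, iterations = 5)),
               "confidence")
  cfg <- adapt_config(threshold = 0.5, iterations = 20, seed = 3,
                      lr = 1e-3)
  a1 <- video_adapt(q$model, frames, cfg)
  a2 <- video_adapt(q$model, frames, cfg)
  expect_identical(a1$params, a2$params)
})

test_that("frozen normalization statistics stay fixed during adaptation", {
  q <- quick_model()
  vid <- generate_video(animal_spec(), motion_spec(n_frames = 5),
                        seed = 42)
  cfg <- adapt_config(threshold = 0.5, iterations = 15, seed = 3,
                      freeze_norm_stats = TRUE)
  a <- video_adapt(q$model, frames_named(vid), cfg)
  expect_identical(a$running, q$model$running)
  cfg2 <- adapt_config(threshold = 0.5, iterations = 15, seed = 3,
                       freeze_norm_stats = FALSE)
  b <- video_adapt(q$model, frames_named(vid), cfg2)
  expect_false(identical(b$running, q$model$running))
})

test_that("the PPLO curriculum schedules 12 epochs and validates levels", {
  q <- quick_model()
  vid <- generate_video(animal_spec(), motion_spec(n_frames = 4),
                        seed = 43)
  frames <- frames_named(vid)
  cfg <- adapt_config(seed = 5, lr = 1e-3)
  m <- pplo_adapt(q$model, frames, config = cfg)
  expect_equal(m$pplo$total_epochs, 12)
  expect_equal(m$pplo$levels, c(0.9, 0.7, 0.5))
  expect_error(pplo_adapt(q$model, frames, levels = numeric()),
               "at least one")
  expect_error(pplo_adapt(q$model, frames, levels = c(0.5, 0.7)),
               "decreasing")
  # a single level with matched budget is exactly video_adapt
  single <- pplo_adapt(q$model, frames, levels = 0.6,
                       epochs_per_level = 3, config = cfg)
  cfg1 <- cfg
  cfg1$threshold <- 0.6
  cfg1$iterations <- 3L * length(frames)
  direct <- video_adapt(q$model, frames, cfg1)
  expect_identical(single$params, direct$params)
})

test_that("Kalman smoothing is exact for its motion model and cuts jitter", {
  lin <- tibble::tibble(frame = 1:60, keypoint = "k",
                        x = 2 * (1:60), y = 3 + (1:60), confidence = 1)
  sm <- kalman_smooth(lin)
  expect_lt(max(abs(sm$x[sm$frame > 10] - lin$x[lin$frame > 10])), 0.05)
  noisy <- dplyr::mutate(lin, x = x + rep(c(0.5, -0.5), 30))
  expect_lt(jitter_score(kalman_smooth(noisy)), jitter_score(noisy))
  static <- dplyr::mutate(lin, x = 5, y = 5)
  sms <- kalman_smooth(static)
  expect_lt(max(abs(tail(sms$x, 10) - 5)), 0.05)
  one <- lin[1, ]
  expect_identical(kalman_smooth(one), one)
  # gaps are bridged by prediction-only steps
  gap <- lin
  gap$x[20:25] <- NA; gap$y[20:25] <- NA
  smg <- kalman_smooth(gap)
  expect_true(all(is.finite(smg$x)))
  expect_lt(max(abs(smg$x[20:25] - lin$x[20:25])), 1)
})

test_that("pyramid inference is single-scale-verbatim and permutation invariant", {
  q <- quick_model()
  img <- q$ds$images[[1]]
  single <- pyramid_infer(q$model, img, pyramid_config(64))
  expect_equal(single, infer_pose(q$model, img))
  p1 <- pyramid_infer(q$model, img,
                      pyramid_config(c(48, 64, 96), 0.3, 0.9))
  p2 <- pyramid_infer(q$model, img,
                      pyramid_config(c(96, 48, 64), 0.3, 0.9))
  expect_equal(dplyr::arrange(p1, keypoint), dplyr::arrange(p2, keypoint))
})

test_that("pyramid falls back to the best scale when nothing survives", {
  q <- quick_model()
  img <- q$ds$images[[2]]
  expect_warning(
    p <- pyramid_infer(q$model, img,
                       pyramid_config(c(16, 24), 0.9999999, 0.95)),
    "falling back")
  expect_equal(nrow(p), 12)
})

test_that("lower_median picks the lower middle order statistic", {
  expect_equal(lower_median(c(3, 1, 2)), 2)
  expect_equal(lower_median(c(4, 1, 3, 2)), 2)
  expect_equal(lower_median(5), 5)
})
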