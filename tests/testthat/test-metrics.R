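mk_pair <- function(offsets, names = paste0("k", seq_along(offsets))) {
  truth <- tibble::tibble(image_id = "i1", keypoint = names,
                          x = seq(0, by = 10,
                                  length.out = length(offsets)),
                          y = 0, flag = 2L)
  pred <- truth
  pred$x <- pred$x + vapply(offsets, `[[`, numeric(1), 1)
  pred$y <- pred$y + vapply(offsets, `[[`, numeric(1), 2)
  list(pred = dplyr::select(pred, -flag), truth = truth)
}

test_that("RMSE matches hand computation and penalizes outliers", {
  p <- mk_pair(list(c(3, 4), c(0, 0)))
  expect_equal(pose_rmse(p$pred, p$truth), sqrt(25 / 2))
  expect_equal(pose_rmse(p$truth, p$truth), 0)
  p2 <- p
  p2$pred$x[2] <- p2$pred$x[2] + 100
  expect_gt(pose_rmse(p2$pred, p2$truth), pose_rmse(p$pred, p$truth))
  empty <- p$truth[0, ]
  expect_error(pose_rmse(empty, empty), "no labeled keypoints")
})

test_that("normalized error divides by the reference distance and is scale free", {
  truth <- tibble::tibble(image_id = "i1",
                          keypoint = c("eye", "nose", "tail"),
                          x = c(0, 25, 40), y = 0, flag = 2L)
  pred <- truth; pred$y <- c(5, 5, 5)
  ne <- normalized_error(dplyr::select(pred, -flag), truth,
                         c("eye", "nose"))
  expect_equal(ne, 5 / 25)
  expect_equal(normalized_error(dplyr::select(truth, -flag), truth,
                                c("eye", "nose")), 0)
  t2 <- dplyr::mutate(truth, x = x * 2, y = y * 2)
  p2 <- dplyr::mutate(pred, x = x * 2, y = y * 2)
  expect_equal(normalized_error(dplyr::select(p2, -flag), t2,
                                c("eye", "nose")), ne)
  t0 <- truth; t0$x[2] <- 0
  expect_error(normalized_error(dplyr::select(pred, -flag), t0,
                                c("eye", "nose")), "zero")
})

test_that("OKS closed forms hold", {
  s <- 40; k <- 0.1
  truth <- tibble::tibble(image_id = "i", keypoint = c("a", "b"),
                          x = c(0, 10), y = 0, flag = c(2L, 2L))
  expect_equal(oks(dplyr::select(truth, -flag), truth,
                   sigma_table(default = k), scale = s), 1)
  pred <- truth; pred$x[1] <- pred$x[1] + s * k * sqrt(2)
  t1 <- truth; t1$flag <- c(2L, 0L)
  expect_equal(oks(dplyr::select(pred, -flag), t1,
                   sigma_table(default = k), scale = s), exp(-1))
  expect_equal(oks(dplyr::select(pred, -flag), truth,
                   sigma_table(default = k), scale = s),
               (1 + exp(-1)) / 2)
  t_none <- truth; t_none$flag <- 0L
  expect_error(oks(dplyr::select(pred, -flag), t_none,
                   sigma_table(default = k), scale = s), "undefined")
})

test_that("OKS is invariant to rigid translation and uniform scaling", {
  withr::with_seed(3, {
    truth <- tibble::tibble(image_id = "i", keypoint = paste0("k", 1:5),
                            x = runif(5, 0, 50), y = runif(5, 0, 50),
                            flag = 2L)
    pred <- dplyr::mutate(truth, x = x + rnorm(5), y = y + rnorm(5))
    base <- oks(pred, truth, sigma_table_mouse(), scale = 30)
    sh <- function(d, f) dplyr::mutate(d, x = f(x), y = f(y))
    expect_equal(oks(sh(pred, function(v) v + 17),
                     sh(truth, function(v) v + 17),
                     sigma_table_mouse(), scale = 30), base)
    expect_equal(oks(sh(pred, function(v) v * 3),
                     sh(truth, function(v) v * 3),
                     sigma_table_mouse(), scale = 90), base)
  })
})

test_that("the packaged sigma tables carry the printed constants", {
  sq <- sigma_table_quadruped()
  expect_equal(unname(sq$values["nose"]), 0.026)
  expect_equal(unname(sq$values["left_eye"]), 0.025)
  expect_equal(unname(sq$values["back_left_paw"]), 0.107)
  expect_equal(sq$default, 0.067)
  expect_equal(length(sq$values), 39)
  expect_equal(sigma_of(sigma_table_mouse(), c("anything", "else")),
               c(0.1, 0.1))
  f <- tempfile(fileext = ".json")
  write_sigma_table(sq, f)
  expect_equal(read_sigma_table(f)$values, sq$values)
})

test_that("mAP closed forms and protocol behavior", {
  withr::with_seed(5, {
    truth <- tidyr::expand_grid(image_id = sprintf("i%02d", 1:8),
                                keypoint = paste0("k", 1:4)) |>
      dplyr::mutate(x = runif(32, 0, 50), y = runif(32, 0, 50),
                    flag = 2L)
    perfect <- dplyr::mutate(truth, confidence = 1)
    expect_equal(map_score(perfect, truth), 100)
    far <- dplyr::mutate(perfect, x = x + 1000)
    expect_equal(map_score(far, truth), 0)
    expect_error(map_score(perfect, truth[0, ]), "empty")
  })
})

test_that("hull areas follow convex-hull geometry", {
  sq_track <- tibble::tibble(frame = 1, keypoint = paste0("k", 1:4),
                             x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                             confidence = 1)
  expect_equal(hull_area_series(sq_track)$area, 1)
  with_int <- dplyr::bind_rows(
    sq_track, tibble::tibble(frame = 1, keypoint = "k5", x = 0.5,
                             y = 0.5, confidence = 1))
  expect_equal(hull_area_series(with_int)$area, 1)
  coll <- dplyr::mutate(sq_track, y = 0)
  h <- hull_area_series(coll)
  expect_equal(h$area, 0)
  low <- dplyr::mutate(sq_track,
                       confidence = c(1, 1, 0.01, 0.01))
  h2 <- hull_area_series(low, cutoff = 0.1)
  expect_equal(h2$area, 0)
  expect_true(h2$degenerate)
})

test_that("jitter matches the hand case and vanishes for constant velocity", {
  tr <- tibble::tibble(frame = 1:4, keypoint = "k",
                       x = c(0, 1, 3, 6), y = 0, confidence = 1)
  expect_equal(pose_jitter(tr)$jitter, 2 / 3)
  cv <- tibble::tibble(frame = 1:10, keypoint = "k", x = 2 * (1:10),
                       y = 3 * (1:10), confidence = 1)
  expect_equal(jitter_score(cv), 0)
  static <- dplyr::mutate(cv, x = 1, y = 1)
  expect_equal(jitter_score(static), 0)
  shifted <- dplyr::mutate(tr, x = x + 100, y = y - 50)
  expect_equal(pose_jitter(shifted)$jitter, 2 / 3)
  expect_error(pose_jitter(tr[1:2, ]), "3 frames")
})

test_that("keypoint dropping counts strict threshold violations", {
  tr <- tibble::tibble(frame = 1, keypoint = paste0("k", 1:3),
                       x = 0, y = 0, confidence = c(0.05, 0.2, 0.5))
  expect_equal(keypoint_drop(tr, 0.1)$dropped, 1)
  expect_equal(keypoint_drop(tr, 0)$dropped, 0)
  hi <- dplyr::mutate(tr, confidence = 0.9)
  expect_equal(attr(keypoint_drop(hi, 0.1), "total"), 0)
  # non-increasing as the threshold decreases
  totals <- vapply(c(0.6, 0.3, 0.1, 0),
                   function(th) attr(keypoint_drop(tr, th), "total"),
                   numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("gain reports subtract pre from post with independent signs", {
  pre <- tibble::tibble(video_id = c("a", "b", "c"),
                        map = c(60, 70, 80))
  post <- tibble::tibble(video_id = c("a", "b", "c"),
                         map = c(65, 60, 75))
  g <- gains(pre, post, "a")
  expect_equal(g$adaptation_gain, 5)
  expect_equal(g$robustness_gain, mean(c(5, -10, -5)))
  expect_gt(g$adaptation_gain, 0)
  expect_lt(g$robustness_gain, 0)
  g0 <- gains(pre, pre, "b")
  expect_equal(g0$adaptation_gain, 0)
  expect_equal(g0$robustness_gain, 0)
  expect_error(gains(pre, post, "zz"), "absent")
  expect_equal(glance(g)$adaptation_gain, 5)
})
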