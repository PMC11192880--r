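test_that("identity variant reproduces canonical ground truth on its subset", {
  spec <- animal_spec()
  sub <- c("nose", "spine_mid", "tail_base")
  ds <- generate_dataset(spec, 4, lab_variant(sub), seed = 3)
  j <- dplyr::inner_join(ds$annotations, ds$truth,
                         by = c("image_id", "keypoint"),
                         suffix = c("", "_true"))
  expect_equal(nrow(j), 4 * 3)
  expect_equal(j$x[j$flag == 2], j$x_true[j$flag == 2])
  expect_equal(j$y[j$flag == 2], j$y_true[j$flag == 2])
})

test_that("generation is bit-reproducible per seed, including files", {
  spec <- animal_spec()
  v <- lab_variant(c("nose", "left_ear"), rename_map = c(nose = "snout"),
                   label_noise_sd = 1)
  d1 <- generate_dataset(spec, 3, v, seed = 9)
  d2 <- generate_dataset(spec, 3, v, seed = 9)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$annotations, d2$annotations)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  ann1 <- d1$annotations; attr(ann1, "keypoints") <- d1$keypoints
  ann2 <- d2$annotations; attr(ann2, "keypoints") <- d2$keypoints
  write_coco(ann1, f1, superset = d1$keypoints)
  write_coco(ann2, f2, superset = d2$keypoints)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_dataset(spec, 3, v, seed = 10)
  expect_false(identical(d1$annotations$x, d3$annotations$x))
})

test_that("disjoint renamed variants union back to the canonical super-set", {
  spec <- animal_spec()
  dsA <- generate_dataset(spec, 2,
                          lab_variant(head_kps(),
                                      rename_map = c(nose = "snout")),
                          seed = 1, dataset_id = "A")
  dsB <- generate_dataset(spec, 2, lab_variant(body_kps()), seed = 2,
                          dataset_id = "B")
  cm <- conversion_map(A = c(snout = "nose"), B = character())
  ss <- build_superset(cm, local_vocabs = list(A = dsA$keypoints,
                                               B = dsB$keypoints))
  expect_setequal(ss, spec$keypoints)
})

test_that("variant subsets are validated against the canonical vocabulary", {
  expect_error(generate_dataset(animal_spec(), 2,
                                lab_variant(c("nose", "wing"))),
               "wing")
})

test_that("label noise is truncated at 3 SD", {
  spec <- animal_spec()
  v <- lab_variant("spine_mid", label_noise_sd = 2)
  ds <- generate_dataset(spec, 50, v, seed = 4)
  j <- dplyr::inner_join(ds$annotations, ds$truth,
                         by = c("image_id", "keypoint"),
                         suffix = c("", "_t"))
  expect_true(all(abs(j$x - j$x_t) <= 6 + 1e-12))
  expect_true(all(abs(j$y - j$y_t) <= 6 + 1e-12))
})

test_that("linear video motion covers the expected displacement", {
  spec <- animal_spec(image_size = c(160, 160))
  v <- generate_video(spec, motion_spec("linear", speed = 2,
                                        n_frames = 50), seed = 5)
  cent <- v$track |>
    dplyr::group_by(frame) |>
    dplyr::summarise(cx = mean(x), cy = mean(y))
  disp <- sqrt(diff(range(cent$cx))^2 + diff(range(cent$cy))^2)
  expect_equal(disp, 98, tolerance = 1e-6)
  expect_equal(length(v$frames), 50)
  expect_equal(dplyr::n_distinct(v$track$frame), 50)
})

test_that("a static video has zero jitter and scale drift compounds", {
  spec <- animal_spec()
  v0 <- generate_video(spec, motion_spec("linear", speed = 0,
                                         n_frames = 10), seed = 6)
  expect_equal(jitter_score(v0$track), 0)
  vd <- generate_video(spec, motion_spec("linear", speed = 0,
                                         n_frames = 50,
                                         scale_drift = 1.01), seed = 6)
  expect_equal(vd$path$scale[50] / vd$path$scale[1], 1.01^49,
               tolerance = 1e-10)
})

test_that("frames where the animal leaves the image are flagged", {
  spec <- animal_spec(image_size = c(48, 48))
  v <- generate_video(spec, motion_spec("linear", speed = 6,
                                        n_frames = 30), seed = 7)
  expect_gt(length(attr(v$track, "flagged_frames")), 0)
  expect_equal(length(v$frames), 30)  # no silent truncation
})

test_that("gait truth has n_cycles contacts and lifts per hoof", {
  g <- generate_gait_track(gait_spec(n_cycles = 5))
  counts <- g$events |>
    dplyr::count(keypoint, event)
  expect_true(all(counts$n == 5))
  expect_equal(nrow(counts), 8)  # 4 hooves x {contact, lift}
})

test_that("gait stance duration equals duty times period", {
  g <- generate_gait_track(gait_spec(duty_factor = 0.6,
                                     stride_period = 30))
  st <- g$events |>
    tidyr::pivot_wider(names_from = event, values_from = frame,
                       values_fn = list) |>
    tidyr::unnest(c(contact, lift))
  # pair each contact with the next lift of the same hoof
  paired <- g$events |>
    dplyr::group_by(keypoint) |>
    dplyr::group_modify(function(d, k) {
      cts <- sort(d$frame[d$event == "contact"])
      lfs <- sort(d$frame[d$event == "lift"])
      tibble::tibble(stance = vapply(cts, function(ct) {
        nx <- lfs[lfs > ct]
        if (length(nx) == 0) NA_real_ else nx[1] - ct
      }, numeric(1)))
    })
  expect_true(all(abs(paired$stance[!is.na(paired$stance)] - 18) <= 1))
})

test_that("degenerate gait inputs behave per contract", {
  g0 <- generate_gait_track(gait_spec(amplitude = 0))
  expect_equal(nrow(g0$events), 0)
  expect_error(gait_spec(stride_period = 3), "undetectable")
  expect_error(gait_spec(duty_factor = 1), "strictly inside")
  expect_error(gait_spec(n_cycles = 0), ">= 1")
})

test_that("projection through the true rename map reproduces canonical truth", {
  spec <- animal_spec()
  v <- lab_variant(c("nose", "left_ear", "tail_base"),
                   rename_map = c(nose = "snout", tail_base = "bott"))
  ds <- generate_dataset(spec, 3, v, seed = 12, dataset_id = "L")
  cm <- conversion_map(L = c(snout = "nose", bott = "tail_base"))
  ss <- build_superset(cm, local_vocabs = list(L = ds$keypoints))
  proj <- project_annotations(ds$annotations, cm[["L"]], ss, dataset = "L")
  j <- dplyr::inner_join(dplyr::filter(proj, flag == 2), ds$truth,
                         by = c("image_id", "keypoint"),
                         suffix = c("", "_t"))
  expect_equal(j$x, j$x_t)
  expect_equal(j$y, j$y_t)
})
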