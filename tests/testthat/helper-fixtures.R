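# Shared fixtures: everything is generated in code from the synthetic-data
# module; expensive artifacts (trained models) are built once per session
# and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) {
    .fixture_env[[name]] <- builder()
  }
  .fixture_env[[name]]
}

head_kps <- function() c("nose", "left_ear", "right_ear",
                         "spine_front", "spine_mid", "spine_rear")
body_kps <- function() c("front_left_paw", "front_right_paw",
                         "back_left_paw", "back_right_paw",
                         "tail_base", "tail_end")

# Two-lab panoptic setting: disjoint subsets, one renamed keypoint.
two_lab_setup <- function(n_per_lab = 20) {
  spec <- animal_spec()
  labA <- lab_variant(head_kps(), rename_map = c(nose = "snout"))
  labB <- lab_variant(body_kps())
  dsA <- generate_dataset(spec, n_per_lab, labA, seed = 21,
                          dataset_id = "labA")
  dsB <- generate_dataset(spec, n_per_lab, labB, seed = 22,
                          dataset_id = "labB")
  cm <- conversion_map(labA = c(snout = "nose"), labB = character())
  ss <- build_superset(cm, local_vocabs = list(labA = dsA$keypoints,
                                               labB = dsB$keypoints))
  pA <- project_annotations(dsA$annotations, cm[["labA"]], ss,
                            dataset = "labA")
  pB <- project_annotations(dsB$annotations, cm[["labB"]], ss,
                            dataset = "labB")
  list(spec = spec, dsA = dsA, dsB = dsB, cm = cm, superset = ss,
       projA = pA, projB = pB,
       merged = merge_datasets(pA, pB),
       images = c(dsA$images, dsB$images))
}

# Panoptic model trained on the two-lab merged set (expensive; memoised).
panoptic_model <- function() {
  fixture("panoptic_model", function() {
    s <- two_lab_setup()
    model <- toy_pose_model(s$superset, channels = 16, seed = 1)
    model <- train_pose_model(model, s$images, s$merged,
                              train_config(steps = 2000, lr = 2e-3,
                                           seed = 5))
    list(model = model, setup = s)
  })
}

# A quickly trained single-lab model for cheap smoke tests.
quick_model <- function() {
  fixture("quick_model", function() {
    spec <- animal_spec()
    ds <- generate_dataset(spec, 18, seed = 11, dataset_id = "quick")
    cm <- conversion_map(quick = character())
    ss <- build_superset(cm, local_vocabs = list(quick = ds$keypoints))
    proj <- project_annotations(ds$annotations, cm[["quick"]], ss,
                                dataset = "quick")
    model <- toy_pose_model(ss, channels = 12, seed = 2)
    model <- train_pose_model(model, ds$images, proj,
                              train_config(steps = 1200, lr = 2e-3,
                                           seed = 3))
    list(model = model, ds = ds, proj = proj, superset = ss)
  })
}

# Random heatmap batch for loss-oracle checks.
random_heatmap_batch <- function(nr = 5, nc = 4, K = 6) {
  logits <- array(rnorm(nr * nc * K), c(nr, nc, K))
  targets <- array(rbinom(nr * nc * K, 1, 0.15), c(nr, nc, K))
  mask <- sample(c(0, 1), K, replace = TRUE)
  structure(list(logits = logits, targets = targets, mask = mask,
                 keypoints = paste0("k", seq_len(K))),
            class = "heatmap_batch")
}

# Exhaustive assignment oracle (minimization) for small matrices.
exhaustive_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf; bestp <- NULL
  for (p in perms(seq_len(ncol(cost)))) {
    s <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (s < best) { best <- s; bestp <- p[seq_len(n)] }
  }
  list(cost = best, assignment = bestp)
}

frames_named <- function(video) {
  setNames(video$frames, sprintf("frame_%06d", seq_along(video$frames)))
}

# Predictions-as-track helper.
as_track <- function(predictions, frame_names, fps = 30) {
  predictions$frame <- match(predictions$image_id, frame_names)
  attr(predictions, "fps") <- fps
  predictions
}
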