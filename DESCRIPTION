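Package: panpose
Title: Panoptic Multi-Dataset Animal Pose Estimation, Adaptation and Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for panoptic animal pose estimation across heterogeneous
    keypoint vocabularies: hand-crafted conversion maps, projection of
    per-lab annotations into a super-set keypoint space with extended
    visibility flags, dataset merging, keypoint-gradient-masked heatmap
    losses, a small trainable heatmap pose network, automatic keypoint
    matching by repeated bipartite assignment, memory-replay fine-tuning,
    unsupervised pseudo-label video adaptation with curriculum and Kalman
    baselines, spatial-pyramid test-time inference, pose evaluation metrics
    (RMSE, normalized error, OKS/mAP, convex-hull area, jitter, keypoint
    dropping, adaptation and robustness gains), and downstream kinematics:
    skeleton-feature action segmentation and gait-event detection with
    stride and stance statistics. A seeded synthetic-data module generates
    images, multi-lab annotation variants, videos and gait trajectories
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    yaml,
    png,
    signal,
    pracma,
    mgcv,
    nnet,
    ggplot2,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
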