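---
title: "Panoptic pose estimation across keypoint vocabularies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panoptic pose estimation across keypoint vocabularies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(panpose)
```

## The problem

Animal pose datasets are fragmented: every lab annotates its own set of
body parts, under its own names, with its own biases. A model trained on
any one vocabulary cannot exploit the others, and fine-tuning a
multi-keypoint model on a dataset that defines only a few keypoints makes
it forget the rest. `panpose` implements a *panoptic* treatment of this
problem: all datasets are projected into one super-set keypoint
vocabulary, undefined keypoints are masked out of the training loss
rather than treated as invisible, and fine-tuning replays the model's own
confident predictions for the keypoints the new dataset does not define.

## The model and its losses

Heatmap pose estimation predicts one score map per keypoint. With target
maps $t_k(i,j) \in \{0,1\}$, predicted probabilities $p_k(i,j)$, and a
per-keypoint gradient mask $n_k$, the package implements the masked
$L_z$ family

$$\mathcal{L}_{L_z} = \sum_{k=1}^{m} \sum_{i,j} n_k \,
  \lVert p_k(i,j) - t_k(i,j) \rVert_z, \qquad z \in \{1, 2\},$$

and the masked cross-entropy

$$\mathcal{L}_{CE} = -\sum_{k=1}^{m} \sum_{i,j} n_k \, t_k(i,j)
  \log p_k(i,j),$$

with probabilities obtained by a softmax over **keypoint channels** at
each pixel (all $M$ channels, including masked ones):
$p_k = \exp l_k / \sum_{k'} \exp l_{k'}$. This is deliberately not the
spatial softmax most pose codebases use; the channel softmax is what
makes masking meaningful — the probability mass assigned to undefined
channels is neither penalized nor encouraged.

The package trains its toy models with the masked $L_2$ loss by
default. The reason is a degeneracy specific to the channel softmax:
cross-entropy only touches cells with a positive target, so the
background probability mass is completely unsupervised and a channel
can develop confident spurious peaks far from its keypoint (we observed
exactly this — channels confidently "owning" patches of background even
on training images). The squared loss penalizes $p_k$ at every
unmasked cell, which drives background toward the uniform floor $1/M$
while leaving masked keypoints untouched; decoded confidences then
separate cleanly (≈1 at a learned keypoint, ≈$1/M$ elsewhere — below
the 0.1 keypoint-drop threshold for the default 12-keypoint
vocabulary). Masked cross-entropy remains available and is used for the
fine-tuning experiments, where it is the conventional heatmap loss and
where its lack of background supervision is exactly what lets naive
fine-tuning collapse unlabeled channels.

The mask is a function of the extended visibility flag alone:

| flag | meaning                         | mask $n_k$ | target |
|-----:|---------------------------------|-----------:|--------|
| $-1$ | not defined in source dataset   | 0          | zero   |
| 0    | defined but not annotated       | 1          | zero   |
| 1    | annotated, not visible          | 1          | zero   |
| 2    | annotated and visible           | 1          | disk   |

Flags 0 and 1 stay *unmasked*: masking them too would stop the model
from learning to assign low scores at genuinely occluded keypoints.

Targets are binary disks of configurable radius (default one map cell)
around the annotated location, matching the $t \in \{0,1\}$ form of the
loss; Gaussian soft targets were rejected to stay literal to that form.

### The toy network

The trainable network is a small convolutional encoder–decoder (two
3×3 conv + pool stages, a per-channel normalization layer with running
statistics, a 3×3 conv, and a 1×1 projection to one logit map per
super-set keypoint at 1/4 input resolution). Forward and backward passes
are written directly in R with im2col/BLAS matrix products and verified
against numerical gradients in the test suite; the optimizer is Adam
with a step-decay schedule (default learning rate $10^{-4}$, decaying at
70% and 90% of the budget). Decoding takes the per-channel argmax with a
deterministic tie-break (lowest $(y,x)$) and, by default, refines the
peak with a 3×3 score-weighted centroid; confidence is the peak channel
probability. Because the channel softmax distributes mass across $K$
channels, an untrained or forgotten channel sits near $1/K \approx 0.08$
for the default 12-keypoint vocabulary — conveniently below the 0.1
keypoint-drop threshold, so dropping counts directly reflect forgetting.

Images taller than 400 px are resized to height 400 preserving aspect
ratio before inference, mirroring the resolution-normalization rule used
for downstream datasets.

## The synthetic-data module

All tests and the acceptance script run exclusively on generated data
with known ground truth. The generator emulates the properties the
method addresses, not photorealism:

* **Body model.** Twelve named keypoints (nose, two ears, three spine
  points, four paws, tail base and end) laid out on an ellipse body; a
  pose parameter vector (center, heading, scale) maps them to image
  coordinates. Default images are 64×64 px with body scale 14 px.
* **Keypoint appearance.** Each keypoint is a dot with a dark surround
  ring, carrying a two-cue signature: six well-separated intensity
  shades crossed with two dot radii (0.11 and 0.26 body scales). Twelve
  distinguishable signatures survive the pixel noise (SD 0.02); features
  scale with the body, so rescaled images change apparent feature size
  exactly as a camera change would — this is what makes the network
  scale-sensitive and the spatial pyramid meaningful.
* **Lab variants.** A variant holds a keypoint subset, a rename map, a
  per-keypoint systematic annotator bias, and label noise (isotropic
  Gaussian truncated at 3 SD so fixtures are bounded).
* **Videos.** Linear, sinusoidal, or random-walk center motion with
  optional per-frame scale drift; frames where the animal leaves the
  image are flagged, never dropped.
* **Gait.** A four-beat walk (hoof phases 0, 0.25, 0.5, 0.75): each hoof
  alternates stance (planted in world coordinates for `duty_factor` of
  the cycle) and swing (advancing one stride length at constant
  velocity while lifted). The linear swing profile makes the fore–aft
  hoof position relative to the back reach its maximum exactly at
  touchdown and its minimum exactly at lift-off, so the analytic event
  schedule is a sharp ground truth. The track is padded with continued
  gait so that trimming 2 s leaves exactly `n_cycles` contacts and
  lifts per hoof; the analysis window is aligned to the largest gap of
  the cyclic event-phase set so no event sits near a window edge. With
  `amplitude = 0` the gait degenerates to rigid translation and the
  ground-truth event set is empty. The `stride_length` field (default
  120 px/cycle) sets the horizontal scale; the spec's field list left
  it implicit.

What passing tests on these fixtures shows: the algorithms are correct
under controlled heterogeneity (disjoint vocabularies, renames, biases,
noise, scale shifts). What they do not show: robustness to deformable
anatomy, occlusion, lighting, or multi-animal scenes — none of which the
generator emulates.

## Vocabulary conversion and matching

Hand-crafted conversion maps (`{dataset: {local: superset}}` JSON,
identity entries omitted) drive projection into the super-set space;
projection is lossless for covered keypoints and marks the rest with
flag $-1$ (coordinates written as 0,0 and ignored by contract). Merging
concatenates projected collections and keeps per-image provenance.

When the mapping is unknown, automatic matching runs zero-shot inference
over an annotated dataset, solves a per-image minimum-Euclidean-cost
bipartite assignment (Hungarian algorithm, written in-package since no
assignment solver ships with the environment; verified against
exhaustive permutation search for sizes ≤ 6), averages the binary match
matrices into an affinity matrix, and solves a final maximum-affinity
assignment. Pairs below `min_affinity = 0.5` — majority-of-images
agreement — are dropped: a wrong pair forces the model to unlearn a
channel, so acceptance is conservative. Unequal vocabulary sizes are
handled by sentinel-cost padding; ties break deterministically by scan
order. Whether per-image matching should pre-filter low-confidence
predictions is genuinely open; it is exposed as `confidence_floor`
(default 0 = keep all).

## Memory replay and video adaptation

`memory_replay_finetune()` substitutes frozen zero-shot predictions
(confidence > 0.7) for keypoints the target dataset does not define
(flag $-1$); everything with flag ≥ 0 keeps its ground truth. The pseudo
labels are generated once and hashed, so label drift is impossible and
immutability is testable. At threshold 1 no substitution can happen and
the run is weight-for-weight identical to naive fine-tuning — the test
suite asserts this exactly.

`video_adapt()` treats the model's own confident predictions
(threshold 0.5) on a novel video as pseudo ground truth and fine-tunes
for 1000 iterations at batch size 1 by default, with normalization
running statistics frozen. The PPLO baseline applies the same step at
confidence levels 0.9, 0.7, 0.5 for four epochs each (12 total),
regenerating pseudo labels at each level; a single level with a matched
budget reduces exactly to `video_adapt()`. The constant-velocity Kalman
filter (forward filtering per keypoint, prediction-only steps over
gaps) is provided as the post-processing baseline that does not touch
model weights.

## Spatial-pyramid inference

`pyramid_infer()` runs the model at several target heights, projects
predictions back to original pixels, discards scales whose mean
confidence falls below threshold, and then discards outlier scales by
cosine similarity against the elementwise-median keypoint vector. The
similarity is computed on coordinate vectors *centered on their own
centroid*: the filter's vectorization was left undefined by its source,
and centering makes the test translation-invariant, which is the
property one wants when scales disagree mainly by a shift. Survivors are
aggregated by the elementwise lower median (deterministic for even
counts); if nothing survives, the highest-confidence scale is returned
with a warning. Scale lists accept `"A:B:S"` range syntax with an
exclusive endpoint.

## Metrics

RMSE (no confidence filtering — outliers are penalized), normalized
error (RMSE over a ground-truth reference distance such as eye-to-nose),
OKS with per-keypoint falloff constants (the packaged quadruped table
carries the 39 printed constants, 0.067 for unlisted names; the mouse
table is 0.1 throughout), single-instance COCO-protocol mAP (101-point
interpolated precision over OKS thresholds 0.50:0.05:0.95, cross-checked
against an independent numpy implementation shipped in
`inst/oracle/coco_eval.py`), convex-hull body area, jitter, keypoint
dropping (strictly below threshold; 0.1 bottom-up, 0.05 top-down), and
adaptation/robustness gains. Two interpretation points are worth
recording: "speed" in the jitter metric is the per-frame Euclidean
displacement magnitude, centered per keypoint per video (the metric's
subscripts index keypoint and example); and evaluation is
single-instance by design — multi-animal OKS matching is out of scope.

## Kinematics

`skeleton_features()` builds the 22-D feature vector (10 distances, 6
interior angles, 4 polygon areas, 2 arena-membership booleans). The
exact identities of the distances/angles/areas are configurable because
the upstream feature table is not printed anywhere; the packaged default
is an anatomically sensible set over the canonical vocabulary, and the
arena polygon is supplied externally (matching how static environment
corners are obtained in practice). `window_classify()` flattens a
31-frame window per labeled frame into a single-hidden-layer network
(`nnet`); weight decay plus an iteration cap stands in for early
stopping, which `nnet` does not support. With the default 22×31 = 682
inputs, hidden widths beyond ~16 make `nnet`'s BFGS memory-heavy; the
tests use width 4, which saturates F1 on separable fixtures.

Gait analysis filters hoof trajectories with a 2nd-order zero-lag
Butterworth low-pass (3 Hz cutoff; forward–backward filtering with
odd-reflection padding so edge transients stay out of the signal),
re-expresses them relative to a back keypoint, trims 2 s at each end,
and detects contacts as peaks / lifts as valleys of the fore–aft
relative position — the hoof is most anterior at touchdown and most
posterior at lift-off. This relative-displacement convention is sharper
than thresholding the vertical trace (stance is a plateau in y, but a
sharp extremum in relative x) and is the package's resolution of the
peak/valley convention question. Adjacent same-type events keep the more
extreme one. Stride lengths use world-frame hoof displacement between
consecutive contacts (centering is for detection only); stances span
contact to the next lift.

## Numerical choices and problem sizes

Tolerances: loss-oracle agreement is exact to 1e-10; Hungarian vs
exhaustive to 1e-12; mAP vs the reference evaluator to 1e-6. Training
experiments in the tests and acceptance script use 64×64 images, a
12-keypoint vocabulary, two 20-image labs, 2000 masked-$L_2$ training
steps at learning rate 2e-3 (panoptic model), 1500-iteration
cross-entropy fine-tunes at learning rate 5e-3 (long enough for naive
fine-tuning to visibly collapse unlabeled channels at toy scale — the
full-scale recipe runs tens of thousands of iterations), 500-iteration
video adaptation, 40-frame videos, and 5-cycle gait tracks — sizes
chosen so the full suite exercises every training path on a single CPU
in a few minutes while leaving comfortable error margins (per-keypoint
held-out RMSE ~1.5–8 px across seeds against a 10 px retention bound
calibrated on these fixtures).

## Known limitations

Single-animal scenes only; the toy network has no pretrained backbone,
so it learns appearance signatures rather than anatomy; pyramid gains
depend on the model being genuinely scale-sensitive (true of small
receptive fields and size-cued fixtures, and of real bottom-up models,
but not of top-down pipelines that re-crop the animal); and the gait
detector assumes a periodic, roughly constant-heading walk within the
analysis window.
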