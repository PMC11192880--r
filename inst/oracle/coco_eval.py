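#!/usr/bin/env python
"""Independent COCO-protocol keypoint mAP evaluator (single instance per
image), used as a cross-check oracle for the R implementation.

Input JSON on argv[1]:
  {
    "sigmas": [k_1, ..., k_K],          # per-keypoint falloff constants
    "thresholds": [0.5, 0.55, ..., 0.95],
    "images": [
      {"id": "...", "scale": s,          # object scale (sqrt bbox area)
       "gt":   [[x, y, v], ...],         # K rows, v = visibility flag
       "pred": [[x, y, c], ...]}         # K rows, c = confidence
    ]
  }

Prints the mAP on the 0-100 scale to stdout.
"""
import json
import sys

import numpy as np


def oks(gt, pred, scale, sigmas):
    gt = np.asarray(gt, dtype=float)
    pred = np.asarray(pred, dtype=float)
    vis = gt[:, 2] > 0
    if not vis.any():
        raise ValueError("no visible ground-truth keypoint")
    d2 = (pred[vis, 0] - gt[vis, 0]) ** 2 + (pred[vis, 1] - gt[vis, 1]) ** 2
    k = np.asarray(sigmas, dtype=float)[vis]
    return float(np.mean(np.exp(-d2 / (2.0 * scale**2 * k**2))))


def average_precision(oks_values, scores, thr):
    order = np.lexsort((np.arange(len(scores)), -np.asarray(scores)))
    tp = np.asarray(oks_values)[order] >= thr
    ctp = np.cumsum(tp)
    cfp = np.cumsum(~tp)
    recall = ctp / len(oks_values)
    precision = ctp / (ctp + cfp)
    # monotone envelope
    for i in range(len(precision) - 2, -1, -1):
        precision[i] = max(precision[i], precision[i + 1])
    rec_thrs = np.linspace(0.0, 1.0, 101)
    idx = np.searchsorted(recall, rec_thrs, side="left")
    prec = np.where(idx < len(precision), precision[np.minimum(idx, len(precision) - 1)], 0.0)
    return float(np.mean(prec))


def main(path):
    with open(path) as fh:
        spec = json.load(fh)
    sigmas = spec["sigmas"]
    thresholds = spec["thresholds"]
    oks_vals, scores = [], []
    for im in spec["images"]:
        oks_vals.append(oks(im["gt"], im["pred"], im["scale"], sigmas))
        pred = np.asarray(im["pred"], dtype=float)
        scores.append(float(pred[:, 2].mean()) if pred.shape[1] > 2 else 1.0)
    aps = [average_precision(oks_vals, scores, t) for t in thresholds]
    print(f"{100.0 * float(np.mean(aps)):.10f}")


if __name__ == "__main__":
    main(sys.argv[1])
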