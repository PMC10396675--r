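---
title: "focalseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{focalseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pulmonary nodules between 3 and 30 mm ("focal opacities") are the lesions a
CT-based lung-cancer screen must find and triage.  Two things make the task
hard on a single axial slice: vessels and bronchi have essentially the same
intensity as nodules, so segmentation cannot rely on thresholding; and once
a nodule is found, benign and malignant lesions differ mainly in size and
shape regularity, which calls for explicit geometric and texture
descriptors rather than intensity statistics.

`focalseg` implements a complete desk-scale version of this workflow:

1. **simulate** — seeded CT-like phantoms with ground truth;
2. **train-seg / segment** — a compact encoder–decoder CNN for per-pixel
   nodule vs background classification;
3. **featurize** — HOG, LBP and convex-hull diameter per segmented nodule,
   fused by concatenation;
4. **classify** — a 17-method classical-classifier benchmark under
   stratified 10-fold cross-validation.

## The segmentation network

The network is a fixed 14-unit stack operating on `(H, W, 3)` inputs with
`H = W` even:

| unit | operation |
|---|---|
| 1 | image input, zero-center (+ 1/255 scaling, see below) |
| 2–7 | 3 × (conv 3×3, 32 filters, stride 1, pad 1 + ReLU) |
| 8 | max-pool 2×2, stride 2 |
| 9–10 | conv 3×3, 32 filters + ReLU |
| 11 | transposed conv 4×4, 32 filters, stride 2, crop 1 per border |
| 12 | conv 1×1, 2 filters |
| 13 | softmax over the two channels |
| 14 | pixel classification (weighted cross-entropy) |

Output resolution equals input resolution: the single ×2 down-sample is
inverted by the ×2 up-sample.  The transposed convolution is computed as
the **exact adjoint** of a stride-2 4×4 convolution; trimming one border
row/column per side ("cropping 1") is precisely what makes the adjoint map
`H/2 → H`, and it is the only reading under which the shapes close.

Numerical choices, all config-exposed through `train_config()`:

* **Input scaling.** The canonical input layer only zero-centers.  With
  8-bit inputs (±~100 after centering) a He-initialized stack saturates its
  softmax immediately; the loss gradient is then dominated by clipped
  regions and SGD at the default learning rate diverges (we confirmed this
  with finite-difference gradient checks, which only match the analytic
  gradients in the non-saturated regime).  The input layer therefore
  zero-centers **and** divides by 255.  This is the package's one deliberate
  deviation from a plain zero-center input, and it is what every modern
  training framework effectively does.
* **Optimizer.** SGD with classical momentum 0.9, learning rate `1e-3`,
  batch 4, 30 epochs by default.  These were fixed a priori and are not
  tuned per dataset.
* **Class weighting.** Nodule pixels are ≪1% of a slice; the default
  pixel-classification loss uses inverse-frequency class weights
  (normalized to mean 1).  An unweighted option exists and collapses to
  all-background on realistic imbalance, which is why it is not the
  default.
* **Split.** 70/30 by slice, stratified on "slice contains a malignant
  nodule", largest-remainder rounding so `round(0.7 n)` slices train
  exactly.  Splitting by pixel would leak texture between sets.
* **Ties.** Arg-max ties in `predict_mask()` go to background — a
  deterministic, conservative rule (an untrained all-zero network predicts
  no nodules, not all nodules).

### Segmentation metrics

`compute_seg_metrics()` reports the standard five-score suite: global
accuracy, mean per-class recall, mean IoU, class-frequency-weighted IoU and
mean boundary-F1.  Boundary pixels are foreground pixels of a class
4-adjacent to the other class; a boundary pixel counts as matched if the
other mask has a boundary pixel within 0.75% of the image diagonal (the
usual convention; at 64×64 this is sub-pixel, so BF is a deliberately harsh
score at small sizes).  Classes absent from both masks contribute a BF of 1
and are skipped by the mean/weighted IoU — so a perfect prediction scores
1.0 on all five metrics even for single-class masks.

## Handcrafted features

**HOG.** Central-difference gradients with replicated edges
(`Gx = I(r,c+1) − I(r,c−1)`), magnitude `sqrt(Gx² + Gy²)` and quadrant-aware
orientation `atan2(Gy, Gx)` folded to [0°, 180°).  (The transposed
`atan2(Gx, Gy)` variant — a 90° relabeling of bins — is available behind
`transposed_angle` for comparison.)  Magnitudes are soft-assigned to the
two nearest of 9 orientation-bin centers placed at multiples of 20°, per
4×4 cell, then L2-normalized over 2×2-cell blocks.  Blocks tile the crop
**without overlap** by default (`block_stride_cells = block_size_cells`):
on the 64×64 featurization crop this yields 8×8 blocks × 36 = 2304
features instead of 8100 with classic 1-cell-stride overlap, which keeps
the subspace-discriminant ensemble (which inverts pooled covariances of
half the feature dimension) tractable.  Set `block_stride_cells = 1` for
the overlapping variant.

**LBP.** The canonical 8-neighbor radius-1 code: threshold each neighbor
against the center with `s(z) = 1 ⇔ z ≥ 0` (ties count as 1, so a constant
window codes 255) and accumulate powers of two clockwise from the top-left
neighbor.  The descriptor is the 256-bin histogram over interior pixels,
optionally restricted to mask pixels and/or normalized.

**Geometric.** The convex hull of the foreground pixel coordinates,
then the maximum pairwise distance between hull vertices (the caliper
diameter).  Crucially this is measured on the component mask at **native
resolution** — the 64×64 crop used by HOG/LBP is size-normalized, so the
diameter is the only size carrier in the fused vector.  A single-pixel mask
has diameter 0; an empty mask is an error.

**Fusion.** Plain concatenation `hog ‖ lbp ‖ geometric`
(2304 + 256 + 1 = 2561 features with defaults).  Any standardization is fit
inside classifiers on their training folds only.

## The classifier bank

Seventeen methods are benchmarked by default (four ensembles, three
decision trees, five SVMs, five KNN variants), each a frozen preset
mirroring the published defaults of the usual interactive
classifier-comparison tool: trees cap splits at 100/20/4; KNN uses
k = 1/10/10/10/10 with Euclidean / Euclidean / Minkowski-3 / cosine /
squared-inverse-weighted-Euclidean metrics; SVMs use polynomial degrees
1/2/3 and Gaussian kernels with scale `sqrt(P)/4` and `sqrt(P)`; ensembles
use 30 learners (bagged deep trees; random half-dimension subspaces over
LDA or 1-NN; RUSBoost with 20-split trees at learning rate 0.1).
`coarse_gaussian_svm` (scale `4 sqrt(P)`) and `coarse_knn` (k = 100) exist
as presets outside the default bank.

Because no SVM/tree/KNN library is available in the target environment,
these learners are implemented in-package: CART with an exhaustive
weighted-Gini split search (C++), the SVM dual solved with `quadprog`
(ridge-stabilized, box constraint 1), and a regularized pooled-covariance
LDA.  One consequential choice: polynomial kernels use the automatic
kernel scale `1/P` — `K(x, z) = (1 + x·z/P)^d` on standardized features.
Without it, dot products of thousands of standardized features put the
dual in a regime where `C = 1` underfits to near-majority voting; with it
the quadratic SVM behaves like its reference implementations.

`cross_validate()` builds seeded stratified folds, pools out-of-fold
predictions into a single confusion matrix per classifier (positive class
= malignant), and derives accuracy, sensitivity, specificity, FPR and
error rate, with `fpr = FP/(FP+TN)` computed independently so the identity
`fpr = 1 − specificity` is a genuine check.  Zero-denominator ratios are
reported as `NA` with an `undefined` flag.  Wall-clock training time and
prediction throughput are recorded for the report tables but never
asserted anywhere — they are hardware noise.

## The phantom generator

`phantom_spec()` describes the simulated world; defaults were fixed once,
from the statistical structure the pipeline must cope with, and are not
tuned against test outcomes:

* 146 slices, one nodule per slice, benign fraction 103/152 ≈ 0.678 —
  the class mix of a 152-nodule cohort;
* benign nodules are discs with diameter drawn from 8–18 px, malignant
  are irregular star-convex blobs (low-order random Fourier perturbation
  of a disc, rescaled so the maximum caliper equals the sampled diameter)
  from 20–34 px.  At the documented nominal scale of 0.7 mm/px these spans
  sit inside the 3–30 mm focal-opacity band; the ranges are disjoint by
  construction and validated as such;
* vessels: elongated wiggly structures rendered at the same intensity as
  nodules (the clinically stated confound), labelled background;
* intensity model: background 30, structures 200, additive Gaussian noise
  σ = 8, quantized to 8 bits.

Shapes are sampled before placement so overlap rejection and edge margins
use the true maximal radius; this guarantees (a) one 8-connected mask
component per nodule and (b) that the rasterized caliper agrees with the
manifest diameter to within ~1.5 px.

What the phantoms deliberately do **not** emulate: lung parenchyma
texture, Hounsfield calibration, 3-D continuity of vessels, partial-volume
effects, or annotation noise.  A green test on phantoms therefore
establishes that the machinery is correct and that the pipeline can
recover a size/shape-coded class signal — not that the paper's clinical
accuracies transfer.

## Determinism

Every stochastic operation derives a private stream from
`(master seed, stage/index)` via `derive_seed()` and restores the caller's
RNG state afterwards.  Identical `(spec, seed)` therefore reproduce
identical slices, splits, folds, initial weights and — because training is
plain single-threaded SGD — identical trained networks, predicted masks
and feature CSVs, byte for byte.

## Known limitations

* The DICOM reader covers single-frame uncompressed little-endian
  monochrome CT only; compressed transfer syntaxes raise format errors.
* The SVM dual is solved densely; fine for the few-hundred-sample regime
  this pipeline targets, not for thousands of samples.
* BF score uses exact pairwise boundary matching (quadratic in boundary
  length); adequate up to 512×512 masks.
* `nodules_per_slice > 1` uses bounded rejection sampling; crowded
  configurations can fail with an explicit placement error rather than
  silently overlapping.
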