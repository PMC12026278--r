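---
title: "Lightweight semantic food segmentation: model, profiling, uncertainty and nutrient estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight semantic food segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodseg)
```

## The problem

Estimating dietary intake from plate photographs needs pixel-accurate food
segmentation, and deployment on phones or embedded devices needs it cheap.
`foodseg` implements a lightweight DeepLabv3+-style encoder–decoder for this
task — an EfficientNet-B1 backbone, a cascaded-waterfall atrous pooling neck
in place of the classic pyramid, and a squeeze-and-excitation (SE) head —
together with everything around it: the training recipe, per-image mean-IoU
evaluation, an exact parameter/MAC profiler, post hoc conformal-prediction
uncertainty maps, and area-proportional nutrient estimation from masks.

The network is implemented natively (R with a few C++ kernels), with
hand-written forward and backward passes, so the whole chain runs and is
testable offline on synthetic plate scenes.

## Architecture

**Backbone.** EfficientNet-B1: a 3×3 stem at stride 2 followed by seven
stages of MBConv blocks (pointwise expansion → depthwise convolution →
internal SE gate → pointwise projection, with residual connections where
shapes allow). Two taps feed the decoder: the stride-4 stage output
(24 channels) and the final stage output (320 channels). The stage that
would reach stride 32 keeps unit stride with its depthwise convolutions
dilated by 2, the standard dense-prediction adaptation, so the high-level
map stays at 1/16 resolution. EfficientNet's 1280-channel top convolution is
kept as (unused) parameters by default: it makes externally supplied
classification-pretrained weight archives loadable without surgery, and the
published complexity figures for this model family include it (see
*Profiling* below). No pretrained weights ship with the package;
initialization is He-style under a user seed.

**Neck.** Two interchangeable context modules over the 320-channel map:

* `build_aspp()` — the classic pyramid: a 1×1 branch, three
  depthwise-separable 3×3 atrous branches at rates 6/12/18, an image-pooling
  branch, a 1×1 projection to 256 channels, and a separable 3×3 refinement.
* `build_cwaspp()` — the lightweight cascaded waterfall: a 1×1 reduction of
  the input to 32 channels, four 3×3 atrous convolutions of 48 channels each
  consuming the previous stage's output (rates 2, 4, 6, 8 — small and
  progressive, avoiding the gridding artifact of large rates), an
  image-pooling branch, and a single 1×1 projection of the concatenation
  (32 + 4·48 + 48 = 272 channels) to 256.

The waterfall widths are not free in this package: they are pinned by
calibration against the published parameter totals of the assembled model
(the search over widths, stage counts, separable/dense variants and
normalization placements has exactly one solution reproducing all printed
figures simultaneously; it is the one shipped in `cwaspp_defaults()`).
Dilation rates do not enter parameter or MAC counts, so the rate set is a
documented choice, not a calibrated one.

**Attention head.** The neck's output 1×1 projection is followed by a
channel-attention block chosen from a registry with *exact* parameter
contracts at 256 channels: SE 8192 (bias-free two-layer bottleneck,
reduction 16), CBAM 8290, ECA 5, GAM 32 870, SIMAM 0, TAM 200, identity 0.
Where a mechanism's published parameter delta does not identify its internal
layout uniquely (GAM, TAM), the shipped block is the minimal standard
variant reproducing the delta and is documented next to its constant in the
source. SE and the identity support training; the others are provided for
inference-mode comparison and profiling.

**Decoder.** Canonical DeepLabv3+: the attended 256-channel map is
bilinearly upsampled ×4, concatenated with the 1×1-reduced (48-channel)
low-level map, fused by a depthwise-separable 3×3 convolution to 256
channels, classified by a biased 1×1 convolution to K classes, and
upsampled ×4 back to input resolution. Ties in `predict_labels()` break
toward the smaller class id.

## Training recipe

`train_config()` defaults follow the published recipe: 100 epochs, batch
size 8, SGD with momentum 0.9 and weight decay $10^{-4}$, cross-entropy
loss over all pixels (the synthetic data are fully labelled; an
ignore-index is deliberately not implemented), inputs resized to 512×512
and scaled to $[0,1]$, random horizontal flips with probability 1/2, and a
polynomial learning-rate decay applied after *every* iteration:

$$\mathrm{lr}(t) = \mathrm{lr}_0\,\bigl(1 - t/T\bigr)^{0.9},$$

reaching exactly 0 at the last iteration. One global seed governs
initialization, shuffling and flips; reproducibility is guaranteed on a
single device.

Numerical choices worth knowing:

* Batch-normalization uses eps $10^{-3}$ in the backbone and $10^{-5}$
  elsewhere. Momentum is 0.1 throughout (the torchvision EfficientNet
  convention). The alternative TF-style 0.01 leaves running statistics so
  stale after short runs that evaluation-mode outputs collapse; with the
  short offline schedules this package targets, 0.1 is the defensible
  choice. Parameter and MAC counts are unaffected.
* Weight decay applies to all parameters (the plain SGD convention);
  normalization scales/shifts are excluded.
* Stochastic depth and dropout are omitted: the offline runs are short, and
  determinism under one seed is worth more here than regularization.

## Evaluation: per-image mean IoU

The headline score is the double mean over images and classes of
$|y \cap \hat y| / |y \cup \hat y|$. Background participates in the class
average. A class absent from both the ground truth and the prediction of an
image is a 0/0; the defining formula is silent on it, so `mean_iou()`
implements three conventions: `"skip"` (exclude from that image's average —
the default), `"one"` (count as a perfect 1), and `"global"` (one
dataset-level confusion matrix). The tests pin the implementation to a
brute-force per-pixel set computation on random maps.

## Complexity profiling and its calibration

`complexity_report()` computes trainable parameters and MACs in closed form
from the configuration; `count_parameters()` independently enumerates the
built tensors, and the tests require the two routes to agree on every
registry model.

Published MAC counts are tool-dependent, so the counting convention is a
first-class, recorded part of every report: convolutions cost
$C_\mathrm{in}/g \cdot k^2$ per output element (biases free), affine
normalizations 4 per input element, module-form bilinear upsampling 11 per
output element, adaptive average pooling (area + 1) per output element,
activations and functional broadcasts 0. Two conventions ship:

* `"full"` counts every operation in every submodule;
* `"published"` (default) additionally excludes the backbone's convolution
  and pooling work while keeping its normalizations.

The published totals for this family of models — 6 793 767 parameters with
2541.89M MACs at 512×512 and 103 classes for the attention-free model, the
per-mechanism deltas, 6.80M/2.54G with SE, 6.79M/2.34G at 74 classes,
1.89G at 11 classes, and 7.44M/3.14G for the classic-pyramid variant — are
reproducible *only* under the second convention. That footprint is exactly
what a hook-based profiler leaves when a backbone implementation wraps its
convolutions in custom classes the profiler does not recognize, a common
failure mode when profiling third-party encoders; the per-class MAC slope
(256·128² for the classifier plus 11·512² for the final upsample,
≈ 7.078M/class) independently confirms the upsampling and classifier
conventions. The calibration is frozen; both conventions are available to
users, and reports always state which one produced them.

Two printing quirks of the published tables are worth recording: the
11-class SE-model parameter total is 6 778 315, which prints as 6.77M under
floor-to-two-decimals but 6.78M under round-half-up (the other tables are
consistent with standard rounding), and the attention MAC deltas reported
here (SE +0.27M, ECA +0.26M, GAM +33.66M) differ from the printed ones by
≤ 0.02M because the published attention wrappers are not reconstructable to
that precision. Parameter deltas are exact.

`pareto_front()` returns the subset of (params ↓, MACs ↓, mIoU ↑)
configurations not dominated by any other, order-stably, verified against
exhaustive dominance enumeration.

## Conformal uncertainty

The softmax stack is treated as a multi-label mask: with threshold
$\hat\lambda$ (default 0.01, the published operating point), every class
scoring above $\hat\lambda$ is selected per pixel. `count_labels()` gives
the per-pixel selected-set size NL, and `variasco()` the heatmap
$V_{ijk} = \hat z_{ijk}/\mathrm{NL}_{ij}$, which is normalized wherever the
set is non-empty. Two conventions the source procedure leaves open are
fixed here and documented: an empty selected set gets $V = 0$ and maximal
scalar uncertainty $u = 1$; and the K planes collapse to the display map
$u = 1 - 1/\mathrm{NL}$ (0 = a certain single label). `calibrate_lambda()`
scans 100 log-spaced thresholds in $[10^{-4}, 0.5]$ and returns the largest
one whose empirical true-label coverage on a calibration set reaches the
target; with no calibration data it returns 0.01. Selection sets grow
monotonically as the threshold falls, and they contain the argmax class
whenever the threshold is below the per-pixel maximum — both properties are
tested on random stacks.

## Nutrient estimation

The plate is the minimum enclosing circle (exact: convex hull + Welzl's
algorithm) of all non-background pixels, radius inflated by 5% — a
documented choice; the source procedure states only that a circular mask
covers the food. Each food's plate-area fraction is scaled linearly by a
reference full-plate serving weight to grams, and grams to
energy/protein/carbohydrate via per-100 g values. Estimates are therefore
linear in area by construction; volume, stacking and occlusion are
explicitly not modelled, which is the dominant error source on real plates
(stacked items are underestimated). Foods missing from the composition
table are flagged and excluded from totals with a warning.

## The synthetic generator, and what passing tests do not show

`generate_scene()` draws a dark tabletop, a bright circular plate, and 1–3
textured elliptical food blobs with per-class base colors and Gaussian
pixel noise (σ = 14 of 255); later blobs occlude earlier ones. Class
frequencies follow 1/rank by default, mirroring the long-tailed imbalance
of real food datasets. Scenes are pure functions of (seed, index); sidecars
record visible per-class areas and plate geometry, giving the nutrition
module an exact ground truth.

These scenes make the segmentation task *color-separable*: they exercise
the full training/evaluation machinery (shape plumbing, gradients,
normalization statistics, schedules) but not the hard parts of real food —
high intra-class variance, inter-class similarity, soft boundaries, fluids,
specular highlights. A passing smoke test shows the implementation trains
and generalizes on learnable structure; it says nothing about benchmark
mIoU on real datasets, which requires the original images and GPU-scale
training and is out of scope here.

Problem sizes used by the shipped tests were chosen to keep the full suite
comfortable on one CPU: the training smoke uses 16 scenes of 3 classes at
side 128 for 30 epochs (batch 8, base rate 0.05), reaching mean IoU well
above the all-background baseline (≈ 0.91 vs ≈ 0.35 in our runs); oracle
and invariant suites use maps of side ≤ 16.

## Known limitations

* Only SE and the identity attention support the backward pass; the other
  registry mechanisms are inference/profiling-only.
* JPEG input is not supported (no JPEG reader in the dependency set); use
  PNG (or TIFF via external conversion). Masks are single-channel indexed
  PNG, with RGB masks accepted on read via palette lookup.
* Training is single-device, full-precision, and deliberately free of
  dropout/stochastic-depth; it targets correctness and reproducibility, not
  wall-clock competitiveness with GPU frameworks.
* The published-convention MAC profile reproduces the printed figures by
  construction of its convention flags; when comparing against other
  codebases, use the `"full"` convention and state it.
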