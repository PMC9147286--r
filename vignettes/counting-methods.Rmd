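---
title: "Counting cotton bolls with full and weak supervision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cotton bolls with full and weak supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The total boll count of a cotton plant is a primary yield-component trait.
Counting bolls by hand in the field is slow and error-prone, and
annotating training images for supervised detectors is the bottleneck:
pixel-accurate instance masks cost the most, one point per boll is an order
of magnitude cheaper, and a single present/absent label per image patch is
cheapest of all. `bollcount` implements a family of counting models that
trade annotation cost against accuracy, together with the tiling,
annotation-handling and evaluation machinery needed to run them end to end
on proximal RGB imagery — and a synthetic scene generator so the whole
pipeline is testable on a CPU without any field data.

## Workflow

Full plant images are decomposed into square, non-overlapping,
zero-padded tiles (`tile_image()`, default 500 px). Counting happens per
tile and the plant total is the sum of tile counts
(`aggregate_plant_count()`). Non-overlapping tiles make the plant total an
exact partition of the point set; the alternative — overlapping tiles —
would require a deduplication rule for bolls seen twice, which the
tile-sum protocol avoids. Points exactly on a tile boundary belong to the
higher-index tile (half-open windows), so per-tile counts always sum to
the number of points.

Annotations travel in the VGG Image Annotator JSON dialect
(`read_via_export()`, `write_scenes()`): polygon regions for instance
masks, point regions for boll centres. Class labels are always *derived*
from the point count (`derive_class_label()`: present iff count > 0),
never stored independently, so the three label granularities cannot drift
apart. Counts are binned as 0, 1–5, 6–10, 11–15; tiles with more than 15
bolls are flagged `dnc` ("did not count") and excluded from training but
never silently deleted. The interval [0, 10] is the *subitizing range*:
the range within which counting models are expected to produce exact
counts. Because field tile sets are dominated by counts 1–5,
`balance_by_rotation()` augments the sparse upper bins with 90°/180°/270°
copies; the rotation convention is fixed (90° = counter-clockwise,
`(x, y) -> (y, side - 1 - x)` in 0-based pixel coordinates) and tested
against pixel-array rotation, because a silent convention mismatch
corrupts every rotated label.

## The three counting models

All three models are built from the same small neural-network engine
(`R/nn.R`): 3×3 and 1×1 convolutions via im2col and BLAS matrix
multiplication, batch normalization, 2×2 max pooling, residual blocks,
dense heads, SGD and Adam. Analytic gradients are verified against central
finite differences in the test suite. Two backbones are provided:
`tiny_cnn` (the default; convolution blocks sized for CPU training) and
`resnet`, a reduced-depth residual backbone behind the same interface.
Full-scale ResNet-50/101 backbones are the natural choice on GPU hardware
but are not reproducible at desk scale, so the package does not pretend to
provide them.

**S-Count** (`build_scount()`, `train_scount()`) is the fully supervised
reference: backbone features feed a 1×1 convolution producing N response
maps (N = 6 by default; hidden layers are ReLU + batch norm) and a fully
connected layer regresses the count, trained with mean squared error
against point-label counts. The regression output is deliberately *not*
clamped during training — clamping inside the loss kills the gradient for
images whose running estimate is negative — and the clamp at zero is
applied only at prediction, where `count_int` rounds half-up.

**WS-Count** (`build_wscount()`, `train_wscount()`) never sees a count. A
presence-absence classifier (PAC) is trained first on tile-level class
labels (binary cross-entropy; for absent tiles every sub-patch is also
absent, so those patches are added as extra negatives — a label-sound
augmentation). The counter is then trained on 21 patches per tile — the
tile, its 4 quarters, its 16 sixteenths, all resized to a common input
side — against two consistency terms:

* classifier consistency `L_PAC-C = mean_b[(1-p_b)|c_b| + p_b max(0, 1-c_b)]`
  (a present patch should count at least one boll, an absent patch zero), and
* spatial consistency `L_SP-C = |C1-C4| + |C1-C16| + |C4-C16|` over the
  three per-scale totals.

One PAC and one counter are shared across all 21 branches; 21 independent
networks would be both statistically wasteful and infeasible at this
scale. Branch counts come through a softplus, so they are positive and
the consistency hinge always has a live gradient. The *reported* losses
are exactly the two forms above and their sum; the *optimizer* weights
them as `w_pac * L_PAC-C + w_sp * L_SP-C` with `w_pac = 21` by default
(equivalently, a branch-summed classifier term). This weighting matters:
with unit weights the spatial term's per-branch subgradient is O(1) while
the averaged classifier term's is O(1/21), and gradient descent collapses
every branch count to zero — spatial consistency is trivially satisfied
by not counting at all. Both weights, the 1-boll margin, and the
prediction rule (scale-1 branch by default, scale-averaged as an option)
are config-exposed.

The mechanism by which WS-Count acquires a number sense is worth stating
plainly: at the 1/16 scale most occupied sub-windows contain a single
boll, so the per-branch floor of one count per present window makes `C16`
approximate the object count, and spatial consistency transports that
estimate up to the full-tile branch used at prediction. The method
therefore subitizes at sub-window granularity — a blob that straddles
several sixteenth windows is counted in each, and several blobs inside
one window are counted once. Both failure modes shrink as objects become
small relative to the 1/16 window, which is also the regime of the
full-scale imagery the tile size was chosen for.

**CountSeg** (`build_countseg()`, `train_countseg()`) sits between the
two: a shared backbone feeds a 1×1 convolution with 60 channels, split in
half between a classification branch and a density branch. The density
map is nonnegative and its sum is the predicted count; the map has stride
4 (two pooling stages), a config consequence of the backbone. Training is
joint under image-level lower-count (ILC) supervision with
`L = L_class + L_spatial + L_global` (unit weights by default,
config-overridable):

* `L_class`: binary cross-entropy on the pooled class score. Pooling is a
  spatial maximum — the simplest pooling that preserves presence
  semantics — and is pluggable.
* `L_global`: `(sum(density) - count)^2` inside the subitizing range;
  beyond it only the lower bound is known, so the hinge
  `max(0, (subitizing_max + 1) - sum)^2` penalizes underestimation alone.
* `L_spatial`: binary cross-entropy between the min-max-normalized
  density map and a pseudo ground-truth peak mask — the `count` strongest
  local maxima of the classification branch's confidence map after
  non-maximum suppression (radius `peak_neighborhood_px`, default 3
  cells). Capping peaks at the known count is what keeps the classifier's
  abundant false-positive peaks out of the supervision. The construction
  is gradient-free; it is computed fresh each step.

Point locations are never consumed; passing them to the trainer is an
error, which makes the supervision contract mechanically checkable.

## Numerical choices

* *Density rectification.* The density output uses softplus rather than a
  hard ReLU: an output-layer ReLU dies irrecoverably once every cell goes
  negative (observed within a few epochs on zero-count-heavy batches),
  whereas softplus keeps the map nonnegative with a live gradient. The
  density head's bias starts at −4 so the initial map is near zero and
  the squared global term cannot explode on the first batches.
* *Spatial-loss gradient.* The min-max bounds of the normalization are
  treated as constants (a stop-gradient), and the 1/range factor is
  floored at 1: early in training the map is near-flat, the true factor
  is enormous, and the unguarded step destroys the density branch. Loss
  *values* are always the exact formulas.
* *Binary cross-entropies* are computed so that a prediction exactly equal
  to its target contributes exactly zero (only the log's argument is
  floored at 1e-12), keeping the documented zero cases exact.
* *Rounding.* `count_int = max(0, floor(count_real + 0.5))` everywhere;
  RMSE is computed on rounded integer counts by default (consistent with
  count semantics), with the real-valued alternative a one-liner away
  since predictions carry both.
* *Median of runs.* For an even number of repeated runs the lower median
  is taken, so the median prediction is always an observed integer count.
* *Determinism.* Every stochastic step (scene synthesis, parameter
  initialization, shuffling) is seeded; one global seed fans out to
  per-stage seeds via `derive_seed()`, so stages are independently
  reproducible and two end-to-end runs with the same config produce
  byte-identical reports for frozen models.

## The synthetic scene generator

`generate_scene()` emulates what the counting problem actually needs:
bright, roughly convex, soft-edged elliptical "bolls" of variable size,
eccentricity and intensity over a darker green-dominant background with
low-frequency multiplicative texture, optional cast shadows, and partial
occlusion (later blobs paint over earlier ones; an occluded boll keeps
its point and clipped mask and stays counted, and rejection sampling
guarantees every boll keeps at least 25% of its area visible). Defaults
describe 500×500 tiles with 0–15 bolls of 12–40 px radius and the
field-typical count-bin imbalance (roughly 25/50/19/6% across the bins,
counts 1–5 dominating); `generate_dataset()` draws counts from those bin
weights. What the generator does *not* emulate: real foliage structure
and self-similar clutter, specular highlights, perspective and depth,
bolls of non-elliptical shape, annotation noise. Passing tests on
synthetic scenes therefore demonstrates that the machinery — losses,
supervision contracts, conservation, calibration — is correct, not that
any model reaches field-grade accuracy; field accuracy requires the real
imagery and GPU-scale backbones.

## The desk-scale benchmark

The test suite and `scripts/acceptance.R` train all three models on a
seeded benchmark of 200 training and 50 held-out 64×64 tiles with counts
0–5 and well-separated blobs (occlusion off). Blob radii are 2.5–5 px,
i.e. the same proportion of the tile side (5–10%) as the full-scale
defaults — keeping object-to-subwindow scale faithful matters, because
WS-Count's subitizing granularity degrades when objects approach the size
of a 1/16 window. Training settings at this scale: S-Count 20 epochs
(Adam, 1e-3), CountSeg 12 epochs (Adam, 1e-3), WS-Count 8 PAC epochs plus
10 counting epochs (Adam, 1e-3); small nets shuffle and converge quickly,
and the suite verifies descent, held-out error, and that weaker
supervision is not better than stronger supervision on average across
seeds (S-Count ≤ CountSeg ≤ WS-Count in RMSE). The package defaults for
the full-scale configurations keep the field-standard optimizers
(SGD 0.001 for CountSeg, Adam 1e-4 for WS-Count).

## Known limitations

* The engine is CPU-bound R; it is sized for method development and
  testing, not for training on thousands of 500×500 field tiles.
* WS-Count inherits the subitizing-granularity bias described above; on
  scenes with objects large relative to the 1/16 window it overcounts
  systematically, and no amount of training removes a bias that is built
  into the supervision signal.
* Pseudo ground truth for CountSeg is only as good as the classification
  branch's confidence map; on hard backgrounds the capped top-k peaks can
  lock onto clutter early in training.
* Mask polygons are parsed and round-tripped but not rasterized into
  training targets; the mask-supervised instance-segmentation route is
  out of scope.
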