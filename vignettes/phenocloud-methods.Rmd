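---
title: "Methods: density-aware stem-leaf segmentation and trait extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-aware stem-leaf segmentation and trait extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Problem

phenocloud measures five phenotypic parameters of field crops — plant
height, leaf length, leaf width, leaf number, and internode length — from
3D point clouds of individual plants, such as the clouds photogrammetry
reconstructs from UAV imagery of tobacco stands. The pipeline is:

1. **Preprocess** the raw scene: remove the ground plane, drop sparse
   outlier points, and thin the cloud.
2. **Segment** every point into stem or leaf with a hierarchical
   point-cloud network.
3. **Measure** traits on the de-normalized, segmented cloud.

Because field datasets of this kind are rarely redistributable, the
package ships a synthetic plant generator whose ground truth is exact;
everything downstream is developed and tested against it.

## Synthetic plants

`make_plant()` builds a plant from a `plant_spec()`: a vertical stem
(cylinder of radius `stem_radius`, height `stem_height`, base at the
origin, z up) and `n_leaves` planar elliptical discs attached at strictly
increasing base heights, pointing outward at spiral-phyllotaxis azimuths
and tilted below the horizontal by `leaf_droop`. Leaves are ellipses by
design: the minimum-area bounding rectangle of an ellipse with semi-axes
L/2 and W/2 has sides exactly L and W, so the geometric ground truth of
the length/width estimator is known analytically. Four anchor points per
leaf (major/minor axis ends) and two stem anchors (base, apex) pin the
exact extremes; the remaining points are uniform on the surface. Gaussian
coordinate noise of scale `noise_sigma` is added last; the returned
`trait_record` is measured on the noiseless geometry.

`make_field()` draws plants from parameter ranges. The defaults are
plausible for tobacco — stems 0.6–1.8 m, 4–10 leaves, blades 0.2–0.6 m
with width 40–70 % of length, droop 10–35°, 2 mm sensor noise — values a
field phenotyping team would recognise; the source material for this
method does not publish its plant-size distribution, so these are the
package's own study conditions. Two couplings keep the plants physical:
leaf count is capped so consecutive bases stay ≥ 0.12 m apart (short
stalks cannot carry ten separated leaves), and base heights are evenly
spaced with ±20 % jitter. What the generator does **not** emulate:
curved/lobed blades, self-occlusion, reconstruction artifacts
(holes, ghost points), registration error, and neighbouring-plant
overlap. Tests passing on synthetic plants therefore demonstrate
correctness of the algorithms under clean geometry, not field-grade
accuracy.

`add_ground_and_outliers()` appends a square ground patch at z = 0
(vertical noise truncated at 3σ) and uniform outliers. Test scenes place
the plant crop 0.3 m above the patch and use a patch large enough that
the ground, as in real field scenes, carries more coplanar points than
any plane through the canopy.

## Preprocessing

*Ground removal* fits a plane by RANSAC: 500 iterations of exact
3-point fits, inliers are points with distance strictly below the 0.2
threshold, and the plane with the most inliers wins; `remove_ground()`
keeps the complement. *Statistical outlier removal* computes each
point's mean distance to its 50 nearest neighbours and drops points
above (mean + 1.0 × sd) of those means. *Uniform downsampling* keeps
every 2nd point in index order — a stride decimation, not a voxel grid,
matching the "sampling rate" notion of common point-cloud editors. The
stages run in that fixed order. Degenerate RANSAC draws (collinear
triples) are redrawn and counted against the iteration budget.

## Segmentation network

The network is a PointNet++-style encoder–decoder over normalized
coordinates. Normalization is per-axis min–max to [0, 1]
(`normalize_cloud()`); the stored minima and ranges make de-normalization
(`x_orig = x_norm × R + min`) exact, which matters because traits are
measured in metres downstream. A degenerate axis stores R = 1 and maps
to 0 so the round-trip stays exact.

Each **set-abstraction (SA)** layer: farthest point sampling keeps half
the points of the previous level (8192 → 4096 → 2048 → 1024 at full
size); each center gathers its K = 16 nearest neighbours (the center is
always its own first neighbour; ties break toward lower indices); a
shared MLP lifts per-point features.

**Local spatial encoding (LSE).** For center `i` and neighbour `k`, the
10-vector `[p_i, p_ik, p_i − p_ik, d(p_i, p_ik)]` is mapped by a shared
MLP to the lifted feature width and concatenated with the neighbour's own
feature, giving position-enhanced features `t_ik` of twice that width.

**Density-aware pooling (DAP).** Every point's neighbourhood density is
`D_i = (1/K) Σ_k 1/(d(p_i, p_ik) + ε)` with ε = 1e-8; densities are
min–max normalized over the level, and a center counts as high-density
iff its normalized density strictly exceeds its neighbours' mean (a
constant field therefore classifies everything low). Two aggregates are
computed for every center: channelwise max pooling, and attention
pooling — a shared linear scorer followed by a per-channel softmax over
the K neighbours, then a weighted sum. The pooled vector concatenates the
density-selected branch first (max for high-density, attention for
low-density) and the complementary branch second, and a fusion MLP
reduces the concatenation to the layer width. Computing both branches
everywhere keeps the layer differentiable and shape-uniform while still
letting density choose which aggregate leads; this resolves the tension
between "select a pooling method per region" and an unconditional
two-branch fusion.

The **decoder** interpolates coarse features onto each finer level with
inverse-distance weights over the 3 nearest coarse points (ε = 1e-8,
weights normalized to sum to 1), concatenates skip features, and applies
a unit MLP (widths 256, 256, 128 top-down). A classifier head (shared
128-wide MLP, dropout 0.5 during training, linear output) emits
per-point stem/leaf logits. Disabling LSE reverts grouping features to
`[relative coordinates, neighbour features]` through the lifted MLP, and
disabling DAP reverts to plain max pooling — together these reproduce a
vanilla SA layer for ablation comparisons.

Widths follow standard segmentation capacity: lift MLPs (64, 128),
(128, 256), (256, 512). Every shared MLP except the attention scorer
and the output layer normalizes its pre-activations per channel over
the points (or grouped neighbours) it is applied to, with learned scale
and shift — the batch-normalization convention of point-cloud networks,
which here amounts to per-cloud instance normalization because a
"batch" is one cloud's points. The same statistics are used at
inference, so predictions stay deterministic and
permutation-equivariant; without this normalization the deep He-initialized
ReLU stack optimizes an order of magnitude more slowly. The first FPS
start index is drawn from the seeded RNG; deeper layers start from the
previous layer's start point, which keeps the forward pass equivariant
under input permutation once the start is pinned.

All of this is implemented directly in R (matrix algebra through BLAS,
neighbourhood kernels in C++) with hand-derived backpropagation; the
test suite verifies every architectural variant against central finite
differences at 1e-6 tolerance.

## Training

Per-point softmax cross-entropy with inverse-frequency class weights
(stem points are ~6× rarer than leaf points), optimized by Adam
(learning rate 0.001, weight decay 1e-4 — the conventional reading of a
"decay rate" hyperparameter — β = 0.9/0.999). The learning rate is
multiplied by 0.7 every 10 epochs; the step length is a common default,
not a documented value, and the optimizer identity (Adam) is likewise a
convention choice, not a claim about the source. Training accuracy is
reported from the training-pass logits with dropout removed at the
output layer — the honest "accuracy of the current model on the training
set" — which costs one extra 2-column matmul per sample. Everything
(shuffling, FPS starts, dropout masks, initialization) runs off a single
seed; identical configurations reproduce identical loss histories to
1e-6.

Evaluation uses the confusion matrix: overall accuracy (percent correct),
per-class intersection-over-union, and mIoU (mean over classes with a
defined IoU; a class absent from both truth and prediction is excluded
rather than scored zero).

## Trait extraction

Measured on the de-normalized cloud, in centimetres:

- **Plant height**: max z − min z over all plant points.
- **Leaf instances**: leaf-labeled points are clustered by Euclidean
  connectivity (points connected within `cluster_eps` = 0.03 m; clusters
  under 50 points dropped). Connectivity clustering is the minimal
  spatial notion that turns a semantic leaf mask into per-leaf regions. Each instance's **base**
  is its point nearest (horizontally) to the vertical stem axis — the
  line through the stem points' centroid — a proxy for the blade-stem
  junction that needs no junction detector.
- **Leaf length/width**: PCA on the instance's 3D points, projection
  onto the first two principal axes (projecting onto the *world* XY
  plane would conflate droop with length), then the minimum-area
  bounding rectangle of the projection by rotating calipers over the
  convex hull; the longer side is length, the shorter width.
- **Leaf number**: the instance count.
- **Internode length**: leaves ranked by base height; the vertical
  distance between the bases of the topmost leaf and the median-rank
  leaf (⌈n/2⌉ ascending). "Upper" and "middle" are not formally defined
  in the field description this follows; rank order is the
  assumption-least reading.

Agreement between predicted and measured traits is scored with R² and
RMSE. Predicted and true per-leaf dimensions are compared through
per-plant means, since no leaf-by-leaf pairing protocol is defined for
the reference measurements.

## Numerical choices and degenerate inputs

- Distances: exact Euclidean, brute force (C++); neighbour ties break
  toward the lower point index, making every neighbourhood deterministic.
- RANSAC boundary: distance equal to the threshold is *not* an inlier.
- A collinear leaf cluster yields width 0 with a warning rather than an
  error; an empty leaf set yields a trait record with leaf number 0 and
  an undefined internode.
- Softmax and cross-entropy are computed with max-shift stabilization;
  probabilities are floored at 1e-12 inside the loss only.
- `resample_to_count()` samples with replacement only when the cloud is
  smaller than the target size.

## Scale of the shipped experiments

The test suite and the acceptance script run the full method at reduced
size — 1024-point inputs, 3 SA layers, a handful of plants, tens of
epochs — chosen so the whole study executes on one ordinary CPU core.
These sizes are the package's study conditions for its own claims
(oracle equivalence, exact round-trips, parameter recovery on clean
geometry, and the direction of the LSE+DAP improvement on a held-out
synthetic split); they do not attempt to reproduce accuracy figures
reported for any external field dataset, which would require the
original data and full-scale training. A caveat on the ablation
comparison: with both models trained to ~99 % accuracy on four clean
plants, held-out mIoU differences of a few points are dominated by
run-to-run variation, so the suite's direction check is made on one
fixed split and seed and should be read as a smoke test of the
comparison machinery, not as evidence about the architectures at field
scale.

## Known limitations

- Brute-force neighbourhood search is O(N²); fine for ≤ 10⁴ points per
  cloud, not for whole-field scenes.
- The synthetic generator's planar leaves make the length/width
  estimator look better than it would on strongly curved blades, where
  a PCA plane projection shortens the blade.
- Internode length follows the median-rank convention above; if a crop
  protocol designates specific leaf positions, the ranking must be
  adapted.
- Single-plant clouds are assumed; no instance segmentation across
  plants is attempted.
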