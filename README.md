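# phenocloud

Automated measurement of plant phenotypic traits from 3D point clouds.

Field phenotyping pipelines reconstruct crop stands (e.g. tobacco) as 3D
point clouds from UAV imagery, then need per-plant measurements that
would otherwise be taken by hand: plant height, leaf length and width,
leaf number, and internode length. phenocloud implements that pipeline
end to end in R:

- **Synthetic plants** (`make_plant()`, `make_field()`): stem-and-leaf
  clouds with per-point semantic labels, per-leaf instance ids and exact
  ground-truth traits, so the whole method is testable without field
  data.
- **Point-cloud I/O and normalization** (`read_cloud()`,
  `write_cloud()`, `normalize_cloud()`): PLY (ASCII/binary) and ASCII
  XYZ; per-axis min–max normalization `x_norm = (x − min_x)/R_x` with an
  exactly invertible de-normalization `x_orig = x_norm · R_x + min_x`.
- **Preprocessing** (`fit_ground_ransac()`, `remove_ground()`,
  `statistical_outlier_filter()`, `uniform_downsample()`): RANSAC
  ground-plane removal (plane `ax + by + cz + d = 0`, inliers by point
  distance `|ax+by+cz+d|/√(a²+b²+c²) <` 0.2, 500 iterations),
  mean-kNN-distance outlier filtering (50 neighbours, 1 sd), stride-2
  decimation.
- **Stem–leaf segmentation** (`segnet_init()`, `train_segnet()`,
  `segment_cloud()`): a hierarchical point-cloud network — farthest
  point sampling halves the cloud per layer, K-nearest-neighbour
  grouping (K = 16), **local spatial encoding**
  `r_ik = MLP(p_i ⊕ p_ik ⊕ (p_i − p_ik) ⊕ d(p_i, p_ik))`, and
  **density-aware pooling**: per-point density
  `D_i = (1/K) Σ_k 1/(d(p_i,p_ik)+ε)` is min–max normalized, centers
  denser than their neighbourhood mean lead with max pooling, sparser
  centers lead with attention pooling
  `F_att = Σ_k softmax(g(t_ik)) · t_ik`, and an MLP fuses
  `F_att ⊕ F_max`. An inverse-distance feature-propagation decoder with
  skip connections restores per-point resolution. Implemented natively
  (BLAS matrix ops + C++ neighbourhood kernels) with hand-derived,
  finite-difference-verified backpropagation and Adam training
  (lr 0.001, weight decay 1e-4, step decay 0.7).
- **Traits and evaluation** (`extract_traits()`, `confusion()`,
  `r_squared()`, `rmse()`): height `H = z_max − z_min`; leaves as
  Euclidean-connectivity instances; length/width from the minimum-area
  bounding rectangle of the PCA-plane projection; internode length as
  the vertical distance between the upper and middle leaf bases;
  OA / per-class IoU / mIoU from the confusion matrix.

## Worked example

```r
library(phenocloud)

# a synthetic tobacco-like plant with known traits
spec <- plant_spec(stem_height = 1.0, n_leaves = 5, noise_sigma = 0,
                   seed = 42)
p <- make_plant(spec)
p$traits
#> <trait_record> height 100.0 cm | 5 leaves | mean length 32.5 cm |
#>   mean width 16.2 cm | internode 32.5 cm

# recover the traits from the labeled geometry
extract_traits(p$cloud)
#> <trait_record> height 100.0 cm | 5 leaves | mean length 32.3 cm |
#>   mean width 16.2 cm | internode 32.5 cm

# segmentation metrics on a hand confusion matrix
cm <- confusion(pred_labels = c(0, 1, 1, 1), true_labels = c(0, 0, 1, 1))
overall_accuracy(cm)   # 75
iou_per_class(cm)      # 50.00000 66.66667
mean_iou(cm)           # 58.33333
```

The printed heights/lengths are centimetres; the recovered leaf length
(32.3 vs 32.5 cm) differs by the disc-sampling error of the minimum
bounding rectangle, under 2 %.

A shell pipeline over cloud files is available through the
`inst/scripts/phenocloud` entry point (subcommands `simulate`,
`preprocess`, `train`, `segment`, `traits`, `evaluate`); run it with no
arguments for usage.

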