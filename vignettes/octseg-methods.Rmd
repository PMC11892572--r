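---
title: "Methods: segmenting 3D OCT images of thick skin into five structural classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting 3D OCT images of thick skin into five structural classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Optical coherence tomography (OCT) of human thick skin (finger pads,
palms) resolves five structural regions in depth order: the probe-gap
space above the skin surface, a thin bright upper stratum corneum, a
thick darker ordered stratum corneum, a brighter cellular epidermis, and
a dimmer dermis whose lower border lies beyond the probing depth.
`octseg` segments 3D OCT intensity volumes into these five classes and
derives layer-thickness morphometry from the result. Because OCT is a
coherent modality, the images carry multiplicative speckle whose
contrast can rival the contrast between layers, which is what makes this
segmentation harder than its ophthalmic counterpart.

The package contains the full workflow: volume IO with physical
geometry, a seeded phantom generator used as ground-truth test bed, a
semi-automatic statistical labeler, 2D and 3D U-Net networks with a
self-contained CPU training engine, block-based inference with
Gaussian-weighted blending, Dice evaluation and thickness estimation.

## Conventions

* Axis order is `(z, y, x)`: depth first (fastest-varying array index),
  then the lateral fast axis (within a B-scan), then the lateral slow
  axis (across B-scans). Indices are 1-based and ranges inclusive, the R
  convention; all crops and block origins follow it.
* The depth axis measures *optical* path length. A full-field volume of
  256 voxels spans 1.2 mm optically, i.e. 4.6875 um per voxel; geometric
  (tissue) distances divide by the tissue refractive index, taken as
  1.4. Acquisitions of 256 x 512 x 512 voxels over 1.2 x 3.0 x 3.0 mm
  are cropped centrally along the slow axis to 256 x 512 x 256, because
  the fibre-probe distorts B-scan borders; which lateral axis to trim is
  a free choice and the package trims the slow axis.
* Intensities are stored as 32-bit floats, labels as 8-bit integers.
  TIFF cannot carry arbitrary float ranges or geometry, so a JSON
  sidecar records the grid, physical extents and the intensity scale;
  NIfTI volumes carry geometry in `pixdim`.

## The speckle phantom

No clinical volumes ship with the package, so all testing rests on a
parametric phantom that emulates the stereotypical appearance of thick
skin (`phantom_params()`, `render_phantom()`, `make_dataset()`):

* **Boundaries.** Four surfaces (tops of classes 2-5). The skin surface
  and the boundary below the upper stratum corneum are smooth (random
  tilt only); the two epidermis boundaries additionally undulate as a
  product of sinusoids in `y` and `x` with random phases — a minimal
  model of the papillary pattern of finger-pad skin. Defaults: amplitude
  3 voxels, period 40 voxels. Consecutive surfaces are separated by the
  layer's geometric thickness times the refractive index (optical
  voxels); ordering is enforced by clamping.
* **Contrast.** Per-class mean intensities `(I1..I5) = (5, 100, 40, 70,
  30)` in relative units, enforcing the thick-skin ordering
  `I2 > I4 > I3`, `I4 > I5`, `I1 < I3`.
* **Attenuation.** Tissue classes decay as
  `exp(-attenuation_per_mm x optical depth below the skin surface)`
  (default 1/mm); the probe gap is not attenuated. Attenuation starts at
  the tissue surface, not the grid top, since class 1 is air/gel.
* **Speckle.** Unit-mean gamma multiplicative noise, i.i.d. per voxel;
  the shape parameter sets the speckle contrast `1/sqrt(shape)`
  (default shape 4, contrast 0.5). Gamma intensity speckle is a
  standard surrogate; the package does not model coherent field
  propagation, point-spread blur, hair follicles or air lacunae, so
  phantom results bound what can be said about clinical data: they
  validate the machinery, not clinical accuracy.
* **Cohorts.** `make_dataset()` draws per-volume layer thicknesses with
  relative SD `thickness_jitter_frac` (default 0.1) and derives one
  sub-seed per volume from the master seed, so datasets are exactly
  reproducible.

Default layer thicknesses are 20 um (upper stratum corneum), 153 um
(ordered stratum corneum) and 137 um (cellular epidermis) — cohort means
reported for healthy thick skin; the dermis fills the remaining depth.

## Semi-automatic labeling

The labeler (`run_semiauto()`) mirrors how an expert seeds a threshold
from a region known to lie inside a layer. For each layer i = 2..5:

1. a cuboid ROI `M_i` strictly inside the layer provides the threshold
   `I_t = mean(M_i) - alpha_i * sd(M_i)` (population SD). `alpha_i` is
   the layer's empirically selected multiplier; it may be negative,
   which places the threshold above the ROI mean — needed for falling
   crossings into darker layers.
2. each lateral column is scanned downward from strictly below the
   previous layer's surface; the first intensity `>=` threshold (rising
   crossing, into a brighter layer) or `<=` threshold (falling) marks
   the layer's upper boundary. Columns without a crossing take the
   deepest scanned index and are flagged.
3. the boundary depth map is median-filtered with an 11 x 11 lateral
   window (reflected borders). A 2D window was chosen over per-B-scan
   1D filtering for lateral isotropy; the window size is the method's
   standard default.
4. the volume below the boundary is despeckled with a 3^3 median filter
   before the next layer is processed (window clipped at borders;
   voxels above the surface untouched).

Labels are then assigned per column from the stacked surfaces, which
guarantees depth-monotone class labels. Crossing directions default to
rising/falling/rising/falling for layers 2-5, matching the
bright/dark/bright/dark contrast sequence of thick skin.

Where a human expert would iterate "inspect, re-select `alpha_i`,
repeat", the package uses explicit parameter configurations plus
automated quality gates against phantom truth in its tests. The default
`alpha = (1.5, -1.5, 1.0, -3)` was calibrated once on the default
phantom contrast/attenuation; the dermis value is large because
attenuation pushes the dermis signal close to the epidermis tail, and
the threshold must sit well above the dermis ROI mean. On noise-free
phantoms the method recovers the planted labels exactly when smoothing
and despeckling are disabled (`w = 1`, `despeckle_window = 1`) and the
thresholds separate adjacent layers; the tests derive such thresholds
from the phantom's own layer statistics, mimicking the expert loop
deterministically. With speckle of shape 8 the defaults give per-class
DSC above 0.9 for classes 3-5 and median boundary errors below 2
voxels.

## The U-Nets

`unet_config()`/`unet()` build a standard five-stage encoder-decoder.
Each encoder stage applies a 3-kernel convolution (padding 1), batch
normalization, ReLU, a second convolution and ReLU; 2x max-pooling
separates stages. Stages generate 32, 64, 128, 256, 512 features
(`width_multiplier` scales all widths for desk-scale instances, e.g.
0.25 gives 8..128). The decoder mirrors the encoder: transposed
convolution (kernel 2, stride 2) upsampling, concatenation with the
symmetric encoder stage's features (skip connections), then
conv/norm/ReLU/conv/ReLU; a final 1x1 convolution emits five raw
per-voxel class scores. The 3D network replaces every 2D operation by
its 3D analogue and pools all three axes (depth 256 and lateral 64 are
both divisible by 2^4). Decoder widths mirror the encoder; "patch
normalization" is read as batch normalization; no softmax inside the
network — scores are normalized downstream where blending needs
comparability.

The training engine is part of the package: im2col/col2im kernels (C++)
map every convolution onto a BLAS matrix product, and batch-norm,
pooling, transposed-conv and softmax cross-entropy backward passes are
implemented in R. Gradients are verified against central differences in
the test suite. The optimizer is Adam with learning rate 0.001 and
betas (0.9, 0.98); the loss is plain per-voxel cross-entropy over all
five classes (no class weighting). He initialization seeds the weights;
all randomness flows from explicit seeds, so training runs are
bit-reproducible on a given platform.

Optional elastic-deformation augmentation (random gaussian-smoothed
displacement fields, bilinear image / nearest-label resampling) is
available for 2D training but off by default.

## Blocks, training and blended inference

Training blocks: the 2D model trains on B-scans (one per slow-axis
index — 256 per standard volume); the 3D model on disjoint full-depth
tiles of 256 x 64 x 64 (32 per volume). For desk-scale 2D runs,
`train_config(crop_lateral = w)` trains on random lateral crops of
width `w` from each B-scan: convolutions translate, so inference still
runs on full B-scans, and the smaller samples buy proportionally more
optimizer steps per unit compute. `blocks_per_epoch` subsamples blocks
per epoch for the same reason: phantom B-scans within a volume are
highly redundant.

Inference (`segment_volume()`, `blend_predict()`): the 2D model
processes each B-scan and the slices reassemble directly. The 3D model
uses overlapping blocks (default lateral stride 32, i.e. 50% overlap);
per-voxel class confidences from all covering blocks are combined with
Gaussian weights `exp(-d^2 / (2 sigma^2))`, `sigma = 16` voxels, `d`
the lateral distance to the block centre (blocks span the full depth,
so overlap exists only laterally). Per-block scores are
softmax-normalized before weighting so that blocks contribute on a
common scale (raw-score blending is available behind a flag); the
blended value is a convex combination of block scores, which the tests
check against a brute-force per-voxel oracle. Each voxel is assigned
the class of the highest blended confidence, ties toward the lowest
class index.

Model selection follows leave-one-out cross-validation over volumes
(`make_cv_plan()`): a seeded draw holds out test volumes entirely (7
volumes with 2 held out give 5 folds), each remaining volume validates
one fold (`train_fold()`), and `select_best()` picks the fold with the
highest mean DSC over the four tissue classes — background is excluded
from the selection metric because it is trivially easy and would
dilute it. The validation metric is the package's choice; epoch count
(default 40) and batch size (8 for 2D, 2 for 3D) are configuration
defaults. Inputs are normalized per volume by the 99th-percentile
intensity, a robust scale under speckle's heavy right tail.

## Evaluation and thickness

`dice()` counts, per class, voxels labeled identically in both volumes:
`DSC_i = 2 n_match / (n_true + n_segm)`, 1 when the class is absent
from both. `layer_thickness()` converts per-column voxel counts of a
layer to geometric micrometres via `count x delta_z_opt / n_refr`
(n_refr = 1.4); columns lacking the layer are excluded from the volume
mean, and the dermis is rejected because its lower border is not
imaged. Per-column counting was preferred over surface-distance
measures because the segmentation output is a label volume.
`cohort_thickness()` reports M +/- sample SD of per-volume means.

## Numerical choices and degenerate inputs

* Fractional boundary depths round half-up at label-assignment time.
* Argmax ties resolve to the lowest class index, everywhere.
* Median filters use reflected borders on depth maps and clipped
  windows inside volumes; even windows are rejected.
* Surfaces are clamped to stay ordered and inside the grid; detection
  failure flags the column instead of erroring.
* Training on an empty set, ROIs outside the volume, non-divisible
  input shapes and class values outside 1..5 raise immediate argument
  errors.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run entirely on phantoms.
The desk-scale training target uses six 128 x 256 x 128 phantoms (same
4.6875 um optical voxel depth as the full field), a width-0.25 2D
U-Net, 40 epochs of 32 sampled B-scans with lateral crop 64 and batch
4, and evaluates the held-out volume — sizes chosen so the whole run
completes in minutes on one CPU core while exercising every stage at
full fidelity. Unit tests use 16-64 voxel grids. The labeler's
acceptance check runs on a 128 x 256 x 128 phantom with speckle shape
8.

## Known limitations

* The phantom's speckle is spatially uncorrelated; real OCT speckle has
  a finite coherence cell, which makes median despeckling somewhat more
  effective here than on clinical data.
* No physics-based signal model (focus, roll-off, multiple scattering),
  no pathological structures; clinical DSC and thickness values cannot
  be reproduced without the original volumes.
* The 3D model is implemented and tested at reduced width/size; CPU
  training of the full-width 3D network is impractical in R and out of
  scope here.
* The labeler's `alpha` defaults are calibrated to the default phantom
  contrast; other contrast configurations need re-selection, exactly as
  the underlying semi-automatic method prescribes.
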