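# octseg

Segmentation of 3D optical coherence tomography (OCT) images of human
thick skin into five structural classes, with layer-thickness
morphometry.

OCT volumes of finger-pad (thick) skin resolve, in depth order: the
probe-gap space above the skin (class 1), a thin bright **upper stratum
corneum** (2), a thick darker **ordered stratum corneum** (3), a
brighter **cellular epidermis** (4) and a dimmer **dermis** (5) whose
lower border lies beyond the probing depth. Segmenting these layers is
the gateway to non-invasive skin morphometry — e.g. stratum corneum and
epidermis thickness — but OCT speckle has contrast comparable to the
layer contrast itself, so naive thresholding fails and the package
combines statistical boundary detection with convolutional networks.

`octseg` implements the complete workflow in R:

* **Volume IO** — TIFF stacks and NIfTI with physical voxel geometry
  (JSON sidecar), central cropping of distorted B-scan borders
  (`read_volume()`, `write_volume()`, `central_crop()`).
* **Speckle phantom generator** — seeded, layered thick-skin phantoms
  with papillary boundary undulation, exponential depth attenuation and
  gamma speckle, plus ground-truth labels (`phantom_params()`,
  `render_phantom()`, `make_dataset()`).
* **Semi-automatic labeler** — per-layer ROI statistics, threshold
  `I_t = mean(M_i) − α_i · sd(M_i)`, per-column boundary scans, median
  smoothing and despeckling, iterated over layers (`run_semiauto()`).
* **2D and 3D U-Nets** with a self-contained CPU training engine
  (im2col convolutions on BLAS, batch norm, Adam lr 0.001, betas
  (0.9, 0.98), cross-entropy; `unet()`, `fit_unet()`), leave-one-out
  cross-validation over volumes (`make_cv_plan()`, `train_fold()`,
  `select_best()`).
* **Block inference with Gaussian blending** — B-scan-wise 2D inference
  and overlapping 256×64×64 3D blocks recombined with
  `w = exp(−d²/(2σ²))`, σ = 16 voxels (`segment_volume()`,
  `blend_predict()`).
* **Evaluation** — per-class Sørensen–Dice
  `DSC_i = 2 n_match / (n_true + n_segm)` (`dice()`) and geometric
  layer thickness `count · Δz_opt / n` with tissue refractive index
  n = 1.4 (`layer_thickness()`, `cohort_thickness()`).

A thin command-line wrapper over these functions is installed at
`inst/cli/octseg.R` (subcommands `phantom`, `label`, `train`,
`segment`, `evaluate`, `thickness`, `pipeline`); `run_pipeline()` runs
the same stages from a YAML config with a JSON run manifest.

## Worked example

Generate a speckled phantom, label it semi-automatically, and measure
the ordered stratum corneum thickness:

```r
library(octseg)

g  <- voxel_geometry(128, 256, 128, 0.6, 1.5, 0.75)   # 4.6875 um/voxel
ph <- render_phantom(phantom_params(geometry = g, speckle_shape = 8,
                                    seed = 3))
res <- run_semiauto(ph$volume, phantom_rois(ph))
dice(ph$truth, res$labels)
#> Sørensen–Dice coefficients:
#>   background 0.9999  (true 491520, segm 491579, match 491511)
#>   upper_sc   0.9198  (true 195777, segm 229774, match 195709)
#>   ordered_sc 0.9812  (true 1497313, segm 1484779, match 1463079)
#>   epidermis  0.9746  (true 1341027, segm 1366484, match 1319320)
#>   dermis     0.9636  (true 668667, segm 621688, match 621681)
#>   mean over tissue classes 2-5: 0.9598

layer_thickness(ph$truth, 3)$mean_um
#> [1] 152.9945
```

The phantom planted a 153 um ordered stratum corneum; the per-column
voxel count of class 3, converted at 4.6875 um of optical depth per
voxel and divided by the refractive index 1.4, recovers it to a small
fraction of the 15 um axial resolution. Under speckle with contrast
1/sqrt(8) ≈ 0.35 the labeler still reaches Dice overlap above 0.9 for
the three thick layers; the thin upper stratum corneum (≈ 6 voxels) is
the hardest class, exactly as in clinical practice.

Training a desk-scale 2D U-Net on phantoms:

```r
phantoms <- make_dataset(6, phantom_params(geometry = g, seed = 1),
                         seed = 101)
fit <- fit_unet(phantoms[1:5],
                unet_config(dims = 2, width_multiplier = 0.25),
                train_config(epochs = 40, batch_size = 4,
                             blocks_per_epoch = 32, crop_lateral = 64),
                val = phantoms[[6]])
fit$mean_fg_dsc        # mean DSC over the four tissue classes
plot(fit)              # training-loss curve
pred <- predict(fit, phantoms[[6]]$volume)
```

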