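test_that("phantom parameters enforce the thick-skin contrast ordering", {
  expect_error(
    phantom_params(layer_mean_intensity = c(`1` = 5, `2` = 30, `3` = 40,
                                            `4` = 70, `5` = 30)),
    "ordering")
  expect_error(phantom_params(speckle_shape = 0), "speckle_shape")
  expect_error(small_params(layer_thickness_um = c(`2` = 500, `3` = 600,
                                                   `4` = 700)),
               "exceed")
})

test_that("boundary surfaces are ordered with the planted optical gaps", {
  # geometric 153 um at n = 1.4 over 4.6875 um voxels: 45.696 voxels
  g <- voxel_geometry(256, 64, 32, 1.2, 3.0 * 64 / 512, 3.0 * 32 / 512)
  pp <- phantom_params(geometry = g, seed = 42,
                       undulation_amplitude_vox = 0)
  set.seed(42)
  b <- sample_boundaries(pp)
  expect_equal(mean(b[[3]]$z - b[[2]]$z), 153 * 1.4 / 4.6875,
               tolerance = 1e-6)
  # with sinusoidal undulation the expected gap holds to within a voxel
  pu <- phantom_params(geometry = g, seed = 42)
  set.seed(42)
  bu <- sample_boundaries(pu)
  expect_equal(mean(bu[[3]]$z - bu[[2]]$z), 153 * 1.4 / 4.6875,
               tolerance = 0.03)
  expect_true(all(b[[1]]$z <= b[[2]]$z))
  expect_true(all(b[[2]]$z <= b[[3]]$z))
  expect_true(all(b[[3]]$z <= b[[4]]$z))
  # determinism
  set.seed(42); b2 <- sample_boundaries(pp)
  expect_identical(b, b2)
})

test_that("zero undulation gives planar epidermis boundaries", {
  pp <- small_params(undulation_amplitude_vox = 0, tilt_amplitude_vox = 0)
  set.seed(1)
  b <- sample_boundaries(pp)
  for (k in 1:4) expect_lt(diff(range(b[[k]]$z)), 1e-9)
})

test_that("noise-free rendering is attenuated piecewise-constant", {
  pp <- small_params()
  ph <- render_phantom(pp, noise = FALSE)
  # within each layer at fixed depth the signal is constant up to
  # per-column surface offsets; with zero attenuation it is constant
  pp0 <- small_params(attenuation_per_mm = 0, tilt_amplitude_vox = 0,
                      undulation_amplitude_vox = 0)
  ph0 <- render_phantom(pp0, noise = FALSE)
  for (cl in 1:5) {
    v <- ph0$volume$intensity[ph0$truth$labels == cl]
    expect_lt(diff(range(v)), 1e-9)
    expect_equal(v[1], unname(pp0$layer_mean_intensity[as.character(cl)]))
  }
  # with attenuation the deepest layer is dimmer than its nominal mean
  v5 <- ph$volume$intensity[ph$truth$labels == 5L]
  expect_true(all(v5 < pp$layer_mean_intensity[["5"]]))
})

test_that("rendered intensities reproduce the configured ordering", {
  # Monte-Carlo: per-layer means at shallow depth, >= 1e4 voxels each
  g <- small_geom(64L, 128L, 64L)
  pp <- small_params(geometry = g, attenuation_per_mm = 0, seed = 9)
  ph <- render_phantom(pp)
  m <- vapply(2:5, function(cl)
    mean(ph$volume$intensity[ph$truth$labels == cl]), numeric(1))
  n <- vapply(2:5, function(cl) sum(ph$truth$labels == cl), numeric(1))
  expect_true(all(n >= 1e4))
  se <- pp$layer_mean_intensity[c("2", "3", "4", "5")] /
    sqrt(pp$speckle_shape * n)
  # I2 > I4 > I3 and I4 > I5 with 3-SE slack
  expect_gt(m[1] - m[3], -3 * sqrt(se[1]^2 + se[3]^2))
  expect_gt(m[3] - m[2], -3 * sqrt(se[3]^2 + se[2]^2))
  expect_gt(m[3] - m[4], -3 * sqrt(se[3]^2 + se[4]^2))
})

test_that("truth labels and boundaries are mutually consistent", {
  ph <- render_phantom(small_params(seed = 4))
  rebuilt <- labels_from_surfaces(ph$boundaries, ph$params$geometry)
  expect_identical(rebuilt$labels, ph$truth$labels)
  expect_true(octseg:::labels_monotone(ph$truth$labels))
})

test_that("speckle contrast matches 1/sqrt(shape)", {
  g <- small_geom(64L, 128L, 64L)
  for (shape in c(2, 8)) {
    pp <- small_params(geometry = g, attenuation_per_mm = 0,
                       speckle_shape = shape, seed = 5)
    ph <- render_phantom(pp)
    v <- ph$volume$intensity[ph$truth$labels == 3L]
    expect_gt(length(v), 5e4)
    expect_equal(stats::sd(v) / mean(v), 1 / sqrt(shape), tolerance = 0.1)
  }
})

test_that("planted thickness is recovered from truth labels", {
  # round-trip within one axial resolution (15 um)
  g <- voxel_geometry(256, 64, 32, 1.2, 3.0 * 64 / 512, 3.0 * 32 / 512)
  ph <- render_phantom(phantom_params(geometry = g, seed = 2),
                       noise = FALSE)
  expect_lt(abs(layer_thickness(ph$truth, 3)$mean_um - 153), 15)
  expect_lt(abs(layer_thickness(ph$truth, 4)$mean_um - 137), 15)
})

test_that("make_dataset is seeded, jittered and reproducible", {
  pp <- small_params()
  d1 <- make_dataset(3, pp, seed = 7)
  d2 <- make_dataset(3, pp, seed = 7)
  expect_identical(d1[[2]]$volume$intensity, d2[[2]]$volume$intensity)
  expect_error(make_dataset(0, pp), "n_volumes")
  # jitter draws distinct thicknesses per volume
  th <- vapply(d1, function(p) p$params$layer_thickness_um[["3"]],
               numeric(1))
  expect_gt(diff(range(th)), 0)
  # zero jitter: all volumes share the expected thicknesses
  d0 <- make_dataset(2, small_params(thickness_jitter_frac = 0), seed = 8)
  expect_equal(d0[[1]]$params$layer_thickness_um,
               d0[[2]]$params$layer_thickness_um)
})
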