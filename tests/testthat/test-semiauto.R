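test_that("layer_threshold implements mean - alpha * sd", {
  g <- small_geom(8L, 8L, 8L)
  vol <- oct_volume(array(50, c(8, 8, 8)), g)
  roi <- layer_roi(2, 1, 8, 1, 8, 1, 8)
  expect_equal(layer_threshold(vol, roi, 5), 50)   # zero-SD case
  arr <- array(0, c(8, 8, 8))
  arr[1:4, , ] <- 90; arr[5:8, , ] <- 110          # mean 100, SD 10
  vol2 <- oct_volume(arr, g)
  expect_equal(layer_threshold(vol2, roi, 2), 80)
  # alpha 0 is the plain ROI mean on a speckled phantom layer
  ph <- render_phantom(small_params(seed = 3))
  r3 <- phantom_rois(ph)[[2]]
  expect_equal(layer_threshold(ph$volume, r3, 0),
               mean(ph$volume$intensity[r3$z0:r3$z1, r3$y0:r3$y1,
                                        r3$x0:r3$x1]))
  expect_error(layer_roi(2, 5, 4, 1, 8, 1, 8), "lo <= hi")
})

test_that("boundary detection finds planted noiseless surfaces exactly", {
  ph <- render_phantom(small_params(seed = 2), noise = FALSE)
  I1 <- ph$params$layer_mean_intensity[["1"]]
  I2 <- ph$params$layer_mean_intensity[["2"]]
  s <- detect_upper_boundary(ph$volume, (I1 + I2) / 2, "rising")
  expect_equal(s$z, octseg:::round_half_up(ph$boundaries[[1]]$z))
  expect_false(any(s$flagged))
})

test_that("degenerate thresholds flag or saturate columns", {
  ph <- render_phantom(small_params(seed = 2), noise = FALSE)
  # threshold below the global minimum, rising: first scanned voxel hits
  s <- detect_upper_boundary(ph$volume, -1, "rising", z_start = 3L)
  expect_true(all(s$z == 3))
  expect_false(any(s$flagged))
  # unreachable threshold: flagged at the deepest index
  s2 <- detect_upper_boundary(ph$volume, 1e9, "rising")
  expect_true(all(s2$flagged))
  expect_true(all(s2$z == ph$params$geometry$n_z))
})

test_that("boundary detection tolerates mild speckle", {
  ph <- render_phantom(small_params(seed = 6, speckle_shape = 16))
  I1 <- ph$params$layer_mean_intensity[["1"]]
  I2 <- ph$params$layer_mean_intensity[["2"]]
  s <- detect_upper_boundary(ph$volume, (I1 + I2) / 2, "rising")
  err <- abs(s$z - ph$boundaries[[1]]$z)
  expect_lte(stats::median(err), 2)
})

test_that("smooth_surface equals a brute-force sliding median", {
  set.seed(10)
  z <- matrix(runif(32 * 32, 5, 50), 32, 32)
  s <- boundary_surface(2L, z)
  sm <- smooth_surface(s, 11L)
  expect_equal(sm$z, brute_median2d(z, 11L))
  # median robustness: single-column spike removed from a plane
  zp <- matrix(20, 32, 32); zp[16, 16] <- 40
  expect_true(all(smooth_surface(boundary_surface(2L, zp), 11L)$z == 20))
  # constants unchanged; even window rejected
  expect_equal(smooth_surface(boundary_surface(2L, zp * 0 + 7), 5L)$z,
               zp * 0 + 7)
  expect_error(smooth_surface(s, 4L), "odd")
})

test_that("despeckle_below only touches voxels at or below the surface", {
  ph <- render_phantom(small_params(seed = 8))
  g <- ph$params$geometry
  zs <- matrix(20, g$n_y, g$n_x)
  s <- boundary_surface(3L, zs, g$n_z)
  out <- despeckle_below(ph$volume, s, 3L)
  expect_identical(out$intensity[1:19, , ], ph$volume$intensity[1:19, , ])
  expect_false(identical(out$intensity[20:g$n_z, , ],
                         ph$volume$intensity[20:g$n_z, , ]))
  # nothing below the grid: unchanged
  sbot <- boundary_surface(3L, matrix(g$n_z + 0, g$n_y, g$n_x))
  out2 <- despeckle_below(ph$volume, sbot, 3L)
  expect_identical(out2$intensity[1:(g$n_z - 1), , ],
                   ph$volume$intensity[1:(g$n_z - 1), , ])
  # constant volume unchanged everywhere
  cv <- oct_volume(array(3, octseg:::dims_of(g)), g)
  expect_equal(despeckle_below(cv, s, 3L)$intensity, cv$intensity)
  expect_error(despeckle_below(ph$volume, s, 2L), "odd")
})

test_that("run_semiauto recovers noise-free phantoms exactly", {
  ph <- render_phantom(small_params(seed = 5), noise = FALSE)
  par <- semiauto_params(alpha = calibrated_alphas(ph), w = 1L,
                         despeckle_window = 1L)
  res <- run_semiauto(ph$volume, phantom_rois(ph), par)
  expect_identical(res$labels$labels, ph$truth$labels)
  # boundary error is exactly zero
  for (k in 1:4)
    expect_equal(res$boundaries[[k]]$z,
                 octseg:::round_half_up(ph$boundaries[[k]]$z))
})

test_that("run_semiauto output is always column-monotone and ordered", {
  ph <- render_phantom(small_params(seed = 12, speckle_shape = 2))
  res <- run_semiauto(ph$volume, phantom_rois(ph))
  expect_true(octseg:::labels_monotone(res$labels$labels))
  b <- res$boundaries
  for (k in 1:3) expect_true(all(b[[k]]$z <= b[[k + 1]]$z))
  expect_error(run_semiauto(ph$volume, phantom_rois(ph)[1:3]), "ROI")
})

test_that("boundary recovery degrades monotonically with speckle", {
  med_err <- function(shape, seeds) {
    mean(vapply(seeds, function(sd) {
      ph <- render_phantom(small_params(seed = sd, speckle_shape = shape))
      res <- run_semiauto(ph$volume, phantom_rois(ph))
      stats::median(abs(res$boundaries[[3]]$z - ph$boundaries[[3]]$z))
    }, numeric(1)))
  }
  seeds <- 21:25
  expect_lte(med_err(16, seeds), med_err(2, seeds))
})
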