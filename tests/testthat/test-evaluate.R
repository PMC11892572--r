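test_that("dice is exact on identity, disjoint and counted cases", {
  g <- small_geom(8L, 8L, 8L)
  set.seed(1)
  lab <- label_volume(array(sample(1:5, 512, TRUE), c(8, 8, 8)), g)
  expect_equal(dice(lab, lab)$dsc, rep(1, 5))
  # disjoint supports for a class score 0
  a <- array(1L, c(8, 8, 8)); a[1:4, , ] <- 2L
  b <- array(1L, c(8, 8, 8)); b[5:8, , ] <- 2L
  expect_equal(dice(label_volume(a, g), label_volume(b, g))$dsc[2], 0)
  # 4 true, 6 segm, 3 matched -> 0.6
  t <- array(1L, c(8, 8, 8)); t[1, 1, 1:4] <- 3L
  s <- array(1L, c(8, 8, 8)); s[1, 1, 2:7] <- 3L
  expect_equal(dice(label_volume(t, g), label_volume(s, g))$dsc[3], 0.6)
  expect_error(dice(lab, label_volume(array(1L, c(4, 8, 8)),
                                      small_geom(4L, 8L, 8L))),
               "shapes")
})

test_that("dice matches the brute-force counting oracle and partitions", {
  g <- small_geom(8L, 8L, 8L)
  set.seed(99)
  for (i in 1:20) {
    t <- array(sample(1:5, 512, TRUE), c(8, 8, 8))
    s <- array(sample(1:5, 512, TRUE), c(8, 8, 8))
    r <- dice(label_volume(t, g), label_volume(s, g))
    expect_identical(r$dsc, brute_dice(t, s))
    expect_equal(sum(r$n_true), 512L)    # classes partition the volume
    # symmetry
    r2 <- dice(label_volume(s, g), label_volume(t, g))
    expect_identical(r$dsc, r2$dsc)
  }
  # both-empty class scores 1 by convention
  t1 <- array(1L, c(8, 8, 8))
  expect_equal(dice(label_volume(t1, g), label_volume(t1, g))$dsc,
               rep(1, 5))
})

test_that("layer thickness follows the refractive-index correction", {
  # uniform 46-voxel layer at 4.6875 um/voxel and n = 1.4
  g <- voxel_geometry(256, 8, 8, 1.2, 3.0 * 8 / 512, 3.0 * 8 / 512)
  lab <- array(5L, c(256, 8, 8))
  lab[1:10, , ] <- 1L; lab[11:20, , ] <- 2L; lab[21:66, , ] <- 3L
  lab[67:100, , ] <- 4L
  lv <- label_volume(lab, g)
  th <- layer_thickness(lv, 3)
  expect_equal(th$mean_um, 46 * 4.6875 / 1.4, tolerance = 1e-12)
  expect_true(all(abs(th$per_column - 154.02) < 0.01))
  # linear in count, inverse in n_refr
  expect_equal(layer_thickness(lv, 3, n_refr = 2.8)$mean_um,
               th$mean_um / 2)
  expect_equal(layer_thickness(lv, 2)$mean_um, th$mean_um * 10 / 46)
  expect_error(layer_thickness(lv, 5), "dermis")
})

test_that("columns without the layer are excluded from the mean", {
  g <- small_geom(8L, 2L, 2L)
  lab <- array(1L, c(8, 2, 2))
  lab[5:8, , ] <- 5L
  lab[3:4, 1, 1] <- 3L                    # only one column has layer 3
  lv <- label_volume(lab, g)
  th <- layer_thickness(lv, 3)
  expect_equal(sum(!is.na(th$per_column)), 1L)
  expect_equal(th$mean_um, 2 * delta_z_opt_um(g) / 1.4)
})

test_that("cohort statistics give M +/- sample SD", {
  g <- small_geom(64L, 4L, 4L)
  mk <- function(nvox) {
    lab <- array(5L, c(64, 4, 4)); lab[1:2, , ] <- 1L
    lab[3:(2 + nvox), , ] <- 3L
    label_volume(lab, g)
  }
  # identical volumes: SD 0
  r0 <- cohort_thickness(list(mk(4), mk(4)), 3)
  expect_equal(r0$sd_um, 0)
  # per-volume means {150, 160} -> 155 +/- 7.071
  um_per_vox <- delta_z_opt_um(g) / 1.4
  n1 <- round(150 / um_per_vox); n2 <- round(160 / um_per_vox)
  r <- cohort_thickness(list(mk(n1), mk(n2)), 3)
  expect_equal(r$mean_um, (n1 + n2) / 2 * um_per_vox)
  expect_equal(r$sd_um, stats::sd(c(n1, n2) * um_per_vox))
  # single volume: SD undefined
  expect_true(is.na(cohort_thickness(list(mk(4)), 3)$sd_um))
})

test_that("jittered phantom cohort recovers the planted mean", {
  g <- voxel_geometry(256, 32, 16, 1.2, 3.0 * 32 / 512, 3.0 * 16 / 512)
  pp <- phantom_params(geometry = g, thickness_jitter_frac = 0.05,
                       speckle_shape = Inf)
  ph <- make_dataset(8, pp, seed = 31)
  r <- cohort_thickness(lapply(ph, function(p) p$truth), 3)
  planted <- vapply(ph, function(p) p$params$layer_thickness_um[["3"]],
                    numeric(1))
  se <- stats::sd(planted) / sqrt(length(planted))
  expect_lt(abs(r$mean_um - mean(planted)), max(3 * se, 5))
})
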