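test_that("2D splitting gives one B-scan block per slow-axis index", {
  g <- voxel_geometry(256, 512, 256, 1.2, 3.0, 1.5)
  vol <- oct_volume(array(0, c(256, 512, 256)), g)
  grid <- split_2d(vol)
  expect_equal(n_blocks(grid), 256L)
  expect_equal(grid$block_shape, c(256L, 512L, 1L))
  g1 <- small_geom(4L, 4L, 1L)
  expect_equal(n_blocks(split_2d(oct_volume(array(0, c(4, 4, 1)), g1))), 1L)
})

test_that("2D blocks concatenated in origin order rebuild the volume", {
  g <- small_geom(4L, 6L, 5L)
  arr <- array(seq_len(4 * 6 * 5), c(4, 6, 5))
  vol <- oct_volume(arr, g)
  grid <- split_2d(vol)
  parts <- lapply(seq_len(n_blocks(grid)), function(k)
    octseg:::extract_block(arr, grid$origins[k, ], grid$block_shape))
  expect_identical(array(unlist(parts), dim(arr)), arr)
})

test_that("disjoint 3D tiling partitions the lateral plane", {
  g <- voxel_geometry(256, 512, 256, 1.2, 3.0, 1.5)
  vol <- oct_volume(array(0, c(256, 512, 256)), g)
  grid <- split_3d_disjoint(vol, c(256, 64, 64))
  expect_equal(n_blocks(grid), 32L)
  g2 <- small_geom(16L, 128L, 128L)
  vol2 <- oct_volume(array(0, c(16, 128, 128)), g2)
  expect_equal(n_blocks(split_3d_disjoint(vol2, c(16, 64, 64))), 4L)
  cov <- coverage_count(split_3d_disjoint(vol2, c(16, 64, 64)))
  expect_true(all(cov == 1L))
  # whole volume as one block
  expect_equal(n_blocks(split_3d_disjoint(vol2, c(16, 128, 128))), 1L)
  expect_error(split_3d_disjoint(vol2, c(16, 60, 64)), "divisible")
  expect_error(split_3d_disjoint(vol2, c(8, 64, 64)), "depth")
})

test_that("overlapping 3D blocks cover every voxel", {
  g <- small_geom(16L, 128L, 128L)
  vol <- oct_volume(array(0, c(16, 128, 128)), g)
  grid <- split_3d_overlap(vol, c(16, 64, 64), c(32, 32))
  cov <- coverage_count(grid)
  expect_true(all(cov >= 1L))
  # interior voxels are covered by 2 blocks per lateral axis (4 total)
  expect_equal(cov[8, 64, 64], 4L)
  # stride = block dims reduces to the disjoint tiling
  gd <- split_3d_overlap(vol, c(16, 64, 64), c(64, 64))
  expect_equal(gd$origins, split_3d_disjoint(vol, c(16, 64, 64))$origins)
  # random valid shapes keep full coverage
  set.seed(3)
  for (i in 1:5) {
    by <- sample(c(16L, 32L, 64L), 1); bx <- sample(c(16L, 32L, 64L), 1)
    st <- c(sample(seq_len(by), 1), sample(seq_len(bx), 1))
    expect_true(all(coverage_count(
      split_3d_overlap(vol, c(16L, by, bx), st)) >= 1L))
  }
  expect_error(split_3d_overlap(vol, c(16, 64, 64), c(0, 32)), "positive")
  # origins sorted lexicographically
  expect_true(!is.unsorted(order(grid$origins[, 1], grid$origins[, 2],
                                 grid$origins[, 3])))
})

test_that("gaussian weights follow the closed form", {
  bp <- blend_params(sigma_vox = 16)
  org <- c(1, 1, 1); bs <- c(16, 33, 33)
  ctr <- org + (bs - 1) / 2
  expect_equal(gaussian_weight(ctr, org, bs, bp), 1.0)
  expect_equal(gaussian_weight(ctr + c(0, 16, 0), org, bs, bp),
               exp(-1 / 2))
  # symmetric under lateral reflection about the centre
  expect_equal(gaussian_weight(ctr + c(0, 5, -7), org, bs, bp),
               gaussian_weight(ctr + c(0, -5, 7), org, bs, bp))
  # depth does not matter in lateral mode
  expect_equal(gaussian_weight(ctr + c(7, 0, 0), org, bs, bp), 1.0)
  expect_error(gaussian_weight(c(0, 1, 1), org, bs, bp), "outside")
})

test_that("single-block blending equals direct classification", {
  g <- small_geom(16L, 16L, 16L)
  set.seed(5)
  vol <- oct_volume(array(runif(16^3), c(16, 16, 16)), g)
  net <- unet(unet_config(dims = 3, n_stages = 3, base_features = 2),
              seed = 2)
  grid <- split_3d_disjoint(vol, c(16, 16, 16))
  lab <- blend_predict(vol, net, grid, normalize_scores = FALSE)
  direct <- classify_confidence(predict_block(net, vol$intensity))
  expect_identical(lab$labels, direct)
})

test_that("blended confidences match a brute-force weighted-sum oracle", {
  g <- small_geom(8L, 64L, 64L)
  vol <- oct_volume(array(0, c(8, 64, 64)), g)
  grid <- split_3d_overlap(vol, c(8, 32, 32), c(16, 16))
  bp <- blend_params(sigma_vox = 8)
  K <- 5L
  set.seed(11)
  blockscores <- lapply(seq_len(n_blocks(grid)), function(k)
    matrix(runif(8 * 32 * 32 * K), ncol = K))
  counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })
  score_fun <- function(block) blockscores[[counter()]]
  lab <- octseg:::blend_scores(vol, grid, score_fun, bp, K)

  # oracle: per voxel, loop over all covering blocks
  blended <- array(0, c(8, 64, 64, K))
  wsum <- array(0, c(8, 64, 64))
  for (k in seq_len(n_blocks(grid))) {
    o <- grid$origins[k, ]
    sc <- array(blockscores[[k]], c(8, 32, 32, K))
    for (yy in seq_len(32)) for (xx in seq_len(32)) {
      vy <- o[2] + yy - 1L; vx <- o[3] + xx - 1L
      w <- gaussian_weight(c(o[1], vy, vx), o, grid$block_shape, bp)
      blended[, vy, vx, ] <- blended[, vy, vx, ] + w * sc[, yy, xx, ]
      wsum[, vy, vx] <- wsum[, vy, vx] + w
    }
  }
  blended <- blended / as.vector(wsum)
  oracle_lab <- array(max.col(matrix(blended, ncol = K),
                              ties.method = "first"), c(8, 64, 64))
  expect_identical(lab$labels, array(as.integer(oracle_lab), c(8, 64, 64)))

  # convexity: blended values lie within the per-block score range
  expect_true(all(blended <= max(vapply(blockscores, max, numeric(1)))))
  expect_true(all(blended >= min(vapply(blockscores, min, numeric(1)))))
})

test_that("constant-score inputs give constant labels (no tile seams)", {
  g <- small_geom(8L, 64L, 64L)
  vol <- oct_volume(array(0, c(8, 64, 64)), g)
  grid <- split_3d_overlap(vol, c(8, 32, 32), c(16, 16))
  sc <- matrix(rep(c(0.1, 0.5, 0.2, 0.1, 0.1), each = 8 * 32 * 32),
               ncol = 5)
  lab <- octseg:::blend_scores(vol, grid, function(b) sc, blend_params(), 5L)
  expect_true(all(lab$labels == 2L))
})
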