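test_that("cross-validation plan has leave-one-out structure", {
  plan <- make_cv_plan(sprintf("v%d", 1:7), 2, seed = 5)
  expect_length(plan$folds, 5L)
  expect_length(plan$test_ids, 2L)
  for (f in plan$folds) {
    expect_false(any(plan$test_ids %in% c(f$train, f$val)))
    expect_length(f$train, 4L)
  }
  vals <- vapply(plan$folds, function(f) f$val, character(1))
  expect_setequal(vals, setdiff(sprintf("v%d", 1:7), plan$test_ids))
  # each training volume validates exactly once
  expect_equal(anyDuplicated(vals), 0L)
  # determinism; small case
  expect_identical(make_cv_plan(sprintf("v%d", 1:7), 2, seed = 5), plan)
  expect_length(make_cv_plan(1:3, 1, seed = 1)$folds, 2L)
  expect_error(make_cv_plan(1:3, 3, seed = 1), "n_test")
})

test_that("select_best maximizes mean tissue DSC with id tie-break", {
  mk <- function(id, dsc) structure(list(fold_id = id, mean_fg_dsc = dsc),
                                    class = "fold_result")
  folds <- list(mk(1L, 0.8), mk(2L, 0.9), mk(3L, 0.85))
  expect_equal(select_best(folds)$fold_id, 2L)
  expect_equal(select_best(folds[1])$fold_id, 1L)
  ties <- list(mk(2L, 0.9), mk(1L, 0.9))
  expect_equal(select_best(ties)$fold_id, 1L)
  expect_error(select_best(list()), "empty")
})

test_that("a few Adam steps strictly reduce the training loss", {
  g <- small_geom(32L, 32L, 6L)
  ph <- render_phantom(small_params(geometry = g,
                                    gap_depth_vox = 4,
                                    layer_thickness_um = c(`2` = 12,
                                                           `3` = 30,
                                                           `4` = 28),
                                    seed = 2))
  mc <- unet_config(dims = 2, n_stages = 3, width_multiplier = 1 / 16)
  tc <- train_config(epochs = 10L, batch_size = 2L, seed = 3L)
  fit <- fit_unet(list(ph), mc, tc)
  expect_lt(fit$history[10], fit$history[1])
  expect_error(fit_unet(list(), mc, tc), "empty")
})

test_that("training reproduces bit-identical histories under a seed", {
  g <- small_geom(16L, 16L, 4L)
  ph <- render_phantom(small_params(geometry = g, gap_depth_vox = 3,
                                    layer_thickness_um = c(`2` = 8,
                                                           `3` = 14,
                                                           `4` = 12),
                                    undulation_amplitude_vox = 0.5,
                                    seed = 6))
  mc <- unet_config(dims = 2, n_stages = 2, width_multiplier = 1 / 16)
  tc <- train_config(epochs = 3L, batch_size = 2L, seed = 9L)
  f1 <- fit_unet(list(ph), mc, tc)
  f2 <- fit_unet(list(ph), mc, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("a degenerate constant-label target is learned to DSC 1", {
  g <- small_geom(16L, 16L, 4L)
  vol <- oct_volume(array(runif(16 * 16 * 4), c(16, 16, 4)), g)
  truth <- label_volume(array(5L, c(16, 16, 4)), g)
  mc <- unet_config(dims = 2, n_stages = 2, width_multiplier = 1 / 8)
  tc <- train_config(epochs = 200L, batch_size = 4L, seed = 1L)
  fit <- fit_unet(list(list(volume = vol, truth = truth)), mc, tc,
                  val = list(volume = vol, truth = truth))
  expect_equal(fit$val_dsc[5], 1)
})

test_that("3D training runs on tiny tiles and reduces the loss", {
  g <- small_geom(16L, 16L, 16L)
  ph <- render_phantom(small_params(geometry = g, gap_depth_vox = 3,
                                    layer_thickness_um = c(`2` = 8,
                                                           `3` = 14,
                                                           `4` = 12),
                                    undulation_amplitude_vox = 0.5,
                                    undulation_period_vox = 8,
                                    seed = 13))
  mc <- unet_config(dims = 3, n_stages = 2, width_multiplier = 1 / 8)
  tc <- train_config(epochs = 8L, batch_size = 2L, seed = 2L)
  fit <- fit_unet(list(ph), mc, tc, block_shape_3d = c(16L, 8L, 8L))
  expect_lt(fit$history[8], fit$history[1])
})

test_that("elastic augmentation preserves shapes and label range", {
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  lab <- matrix(sample(1:5, 32 * 32, TRUE), 32, 32)
  el <- octseg:::elastic_deform2d(img, lab)
  expect_equal(dim(el$x), dim(img))
  expect_true(all(el$y %in% 1:5))
  expect_true(all(is.finite(el$x)))
})
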