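#' Training configuration
#'
#' Cross-entropy loss over the 5 classes (background included, no class
#' weighting) optimized with Adam.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param betas Adam moving-average coefficients (default `c(0.9, 0.98)`).
#' @param epochs Training epochs (default 40).
#' @param batch_size Blocks per gradient step (default 8 for 2D, 2 for
#'   3D; set explicitly to override).
#' @param blocks_per_epoch Number of training blocks sampled per epoch,
#'   or `NULL` for a full pass over all blocks. Phantom B-scans within a
#'   volume are highly redundant, so a modest subsample per epoch trains
#'   as well as a full pass at a fraction of the cost.
#' @param crop_lateral For 2D training only: width (voxels) of random
#'   lateral crops taken from each training B-scan, or `NULL` for the
#'   full B-scan. Cropping cuts the per-step cost roughly in proportion
#'   while leaving inference on full B-scans unchanged (convolutions
#'   translate), so more optimizer steps fit the same compute budget.
#' @param seed RNG seed for shuffling and augmentation.
#' @param augment_elastic Apply random elastic deformations to 2D
#'   training slices (default off).
#' @param normalize_quantile Per-volume intensity normalization divides
#'   by this intensity quantile (default 0.99).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, betas = c(0.9, 0.98),
                         epochs = 40L, batch_size = NULL,
                         blocks_per_epoch = NULL, crop_lateral = NULL,
                         seed = 1L, augment_elastic = FALSE,
                         normalize_quantile = 0.99) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (length(betas) != 2L || any(betas < 0) || any(betas >= 1))
    stop("betas must be two values in [0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate, betas = betas,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 blocks_per_epoch = blocks_per_epoch,
                 crop_lateral = crop_lateral,
                 seed = as.integer(seed),
                 augment_elastic = isTRUE(augment_elastic),
                 normalize_quantile = normalize_quantile),
            class = "train_config")
}

# accept an oct_phantom or a list(volume=, truth=) pair
as_training_pair <- function(x) {
  if (inherits(x, "oct_phantom")) list(volume = x$volume, truth = x$truth)
  else if (is.list(x) && !is.null(x$volume) && !is.null(x$truth)) x
  else stop("training data must be oct_phantom or list(volume, truth)",
            call. = FALSE)
}

normalize_intensity <- function(arr, q = 0.99) {
  s <- stats::quantile(arr, q, names = FALSE)
  if (s <= 0) s <- max(arr, 1e-12)
  arr / s
}

#' Fit a U-Net to labeled OCT volumes
#'
#' The central fitting routine: decomposes the training volumes into
#' blocks matching the network dimensionality (2D: one B-scan per slow-
#' axis index; 3D: disjoint full-depth tiles), normalizes intensities
#' per volume, and minimizes mean per-voxel softmax cross-entropy with
#' Adam. Deterministic given the seeds in `model_config`/`cfg`.
#'
#' @param data List of training items, each an `oct_phantom` or a
#'   `list(volume, truth)` pair.
#' @param model_config A [unet_config()].
#' @param cfg A [train_config()].
#' @param val Optional single validation item (same forms); per-class
#'   DSC on it is computed after training.
#' @param block_shape_3d Block shape for 3D training (default
#'   `(n_z, 64, 64)` clipped to the volume).
#' @param verbose Print per-epoch loss.
#' @return An object of class `unet_fit`: list with `net`, `history`
#'   (per-epoch mean loss), `val_dsc`, `mean_fg_dsc`, `cfg`.
#' @export
fit_unet <- function(data, model_config = unet_config(),
                     cfg = train_config(), val = NULL,
                     block_shape_3d = NULL, verbose = FALSE) {
  stopifnot(inherits(model_config, "unet_config"),
            inherits(cfg, "train_config"))
  if (length(data) < 1L) stop("empty training set", call. = FALSE)
  data <- lapply(data, as_training_pair)
  dims <- model_config$dims
  batch <- cfg$batch_size %||% if (dims == 2L) 8L else 2L

  # normalized intensity arrays + label arrays
  xs <- lapply(data, function(p)
    normalize_intensity(p$volume$intensity, cfg$normalize_quantile))
  ys <- lapply(data, function(p) p$truth$labels)

  # enumerate training blocks as (volume, block) pairs
  if (dims == 2L) {
    counts <- vapply(xs, function(a) dim(a)[3], integer(1))
    index <- cbind(rep(seq_along(xs), counts),
                   unlist(lapply(counts, seq_len)))
    cw <- cfg$crop_lateral
    get_block <- function(i) {
      v <- index[i, 1]; xi <- index[i, 2]
      x <- xs[[v]][, , xi]; y <- ys[[v]][, , xi]
      if (!is.null(cw) && cw < ncol(x)) {
        o <- sample.int(ncol(x) - cw + 1L, 1L)
        x <- x[, o:(o + cw - 1L)]; y <- y[, o:(o + cw - 1L)]
      }
      list(x = x, y = y)
    }
  } else {
    grids <- lapply(data, function(p) {
      bs <- block_shape_3d %||%
        c(p$volume$geometry$n_z, pmin(64L, p$volume$geometry$n_y),
          pmin(64L, p$volume$geometry$n_x))
      split_3d_disjoint(p$volume, bs)
    })
    counts <- vapply(grids, n_blocks, integer(1))
    index <- cbind(rep(seq_along(xs), counts),
                   unlist(lapply(counts, seq_len)))
    get_block <- function(i) {
      v <- index[i, 1]; k <- index[i, 2]
      g <- grids[[v]]; o <- g$origins[k, ]; b <- g$block_shape
      list(x = extract_block(xs[[v]], o, b),
           y = extract_block(ys[[v]], o, b))
    }
  }
  n_all <- nrow(index)

  net <- unet(model_config, seed = cfg$seed)
  opt <- adam_init(net$params)
  set.seed(cfg$seed + 1L)
  history <- numeric(cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ids <- if (is.null(cfg$blocks_per_epoch)) sample(n_all) else
      sample.int(n_all, cfg$blocks_per_epoch, replace = n_all <
                   cfg$blocks_per_epoch)
    losses <- c()
    for (ofs in seq(1L, length(ids), batch)) {
      take <- ids[ofs:min(ofs + batch - 1L, length(ids))]
      blocks <- lapply(take, get_block)
      if (cfg$augment_elastic && dims == 2L)
        blocks <- lapply(blocks, function(bl) {
          el <- elastic_deform2d(bl$x, bl$y)
          list(x = el$x, y = el$y)
        })
      bd <- dim(blocks[[1]]$x)
      xb <- array(0, c(bd, length(blocks), 1L))
      yb <- integer(prod(bd) * length(blocks))
      for (j in seq_along(blocks)) {
        if (dims == 2L) xb[, , j, 1L] <- blocks[[j]]$x
        else xb[, , , j, 1L] <- blocks[[j]]$x
        yb[(j - 1L) * prod(bd) + seq_len(prod(bd))] <- blocks[[j]]$y
      }
      fw <- unet_forward(net, xb, train = TRUE)
      net$bn <- fw$bn
      ce <- softmax_ce(fw$scores, yb)
      grads <- unet_backward(net, fw$cache, ce$dlogits)
      st <- adam_step(net$params, grads, opt, lr = cfg$learning_rate,
                      beta1 = cfg$betas[1], beta2 = cfg$betas[2])
      net$params <- st$params
      opt <- st$state
      losses <- c(losses, ce$loss)
    }
    history[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs, history[ep]))
  }

  val_dsc <- NULL; mean_fg <- NA_real_
  if (!is.null(val)) {
    val <- as_training_pair(val)
    pred <- segment_volume(net, val$volume,
                           normalize_quantile = cfg$normalize_quantile)
    rep_ <- dice(val$truth, pred)
    val_dsc <- rep_$dsc
    mean_fg <- mean(rep_$dsc[2:5])
  }
  structure(list(net = net, history = history, val_dsc = val_dsc,
                 mean_fg_dsc = mean_fg, cfg = cfg,
                 model_config = model_config),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("unet_fit: %dD U-Net, %d epochs, final loss %.4f\n",
              x$model_config$dims, length(x$history),
              x$history[length(x$history)]))
  if (!is.null(x$val_dsc))
    cat(sprintf("  validation DSC (classes 1-5): %s; mean tissue DSC %.3f\n",
                paste(sprintf("%.3f", x$val_dsc), collapse = " "),
                x$mean_fg_dsc))
  invisible(x)
}

#' @export
summary.unet_fit <- function(object, ...) {
  print(object)
  print(object$net)
  cat("loss history:", paste(sprintf("%.3f", object$history),
                             collapse = " "), "\n")
  invisible(object)
}

#' @export
plot.unet_fit <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "b", xlab = "epoch",
       ylab = "mean cross-entropy", main = "training loss", ...)
  invisible(x)
}

#' @export
predict.unet_fit <- function(object, newdata, ...) {
  segment_volume(object$net, newdata,
                 normalize_quantile = object$cfg$normalize_quantile, ...)
}

#' Segment a full volume with a trained network
#'
#' 2D networks process the volume B-scan by B-scan; 3D networks use
#' overlapping full-depth blocks recombined with Gaussian-weighted
#' confidence blending.
#'
#' @param net A [unet()].
#' @param vol An [oct_volume()].
#' @param stride Lateral stride for overlapping 3D blocks (default 32,
#'   i.e. 50 percent overlap).
#' @param sigma Gaussian blending radius in voxels (default 16).
#' @param block_shape Block shape for 3D inference (default
#'   `(n_z, 64, 64)`).
#' @param normalize_quantile Per-volume intensity normalization quantile
#'   (must match training; default 0.99).
#' @return A [label_volume()].
#' @export
segment_volume <- function(net, vol, stride = c(32L, 32L), sigma = 16,
                           block_shape = NULL,
                           normalize_quantile = 0.99) {
  pre <- function(a) normalize_intensity(a, normalize_quantile)
  if (net$config$dims == 2L) {
    grid <- split_2d(vol)
  } else {
    bs <- block_shape %||% c(vol$geometry$n_z,
                             min(64L, vol$geometry$n_y),
                             min(64L, vol$geometry$n_x))
    grid <- split_3d_overlap(vol, bs, stride)
  }
  blend_predict(vol, net, grid, blend_params(sigma), preprocess = pre)
}

#' Leave-one-out cross-validation plan
#'
#' Holds out `n_test` volumes entirely (seeded random draw), then forms
#' one fold per remaining volume with that volume as the validation
#' object: 7 volumes with 2 held out give 5 folds.
#'
#' @param volume_ids Character or integer ids of the available volumes.
#' @param n_test Number of volumes kept out as the final test sample.
#' @param seed RNG seed.
#' @return An object of class `cv_plan` with `test_ids` and `folds`
#'   (list of `list(train, val)`).
#' @export
make_cv_plan <- function(volume_ids, n_test, seed = 1L) {
  if (n_test >= length(volume_ids))
    stop("n_test must leave at least one training volume", call. = FALSE)
  if (length(volume_ids) - n_test < 2L)
    stop("need at least two training volumes for leave-one-out",
         call. = FALSE)
  set.seed(seed)
  test_ids <- sort(sample(volume_ids, n_test))
  train_pool <- setdiff(volume_ids, test_ids)
  folds <- lapply(seq_along(train_pool), function(i)
    list(train = train_pool[-i], val = train_pool[i]))
  structure(list(volume_ids = volume_ids, test_ids = test_ids,
                 folds = folds, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d volumes, %d held out for test, %d folds\n",
              length(x$volume_ids), length(x$test_ids), length(x$folds)))
  invisible(x)
}

#' Train one cross-validation fold
#'
#' Trains on the fold's training volumes and evaluates per-class DSC on
#' its validation volume. Test volumes never enter: the fold only names
#' training-pool ids.
#'
#' @param fold One element of a [make_cv_plan()]'s `folds`.
#' @param model_config A [unet_config()].
#' @param cfg A [train_config()].
#' @param data Named list mapping volume id to an `oct_phantom` or
#'   `list(volume, truth)`.
#' @param fold_id Integer id recorded in the result.
#' @param ... Passed to [fit_unet()].
#' @return A `fold_result` (a [fit_unet()] result with a `fold_id`).
#' @export
train_fold <- function(fold, model_config, cfg, data, fold_id = 1L, ...) {
  ids <- as.character(fold$train)
  if (length(ids) == 0L) stop("empty training set", call. = FALSE)
  missing <- setdiff(c(ids, as.character(fold$val)), names(data))
  if (length(missing))
    stop("data missing for ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  fit <- fit_unet(data[ids], model_config, cfg,
                  val = data[[as.character(fold$val)]], ...)
  fit$fold_id <- as.integer(fold_id)
  class(fit) <- c("fold_result", class(fit))
  fit
}

#' Select the best fold by validation DSC
#'
#' Maximizes the mean DSC over the four tissue classes; ties are broken
#' toward the lowest `fold_id`.
#'
#' @param folds List of `fold_result`s.
#' @return The winning `fold_result`.
#' @export
select_best <- function(folds) {
  if (length(folds) == 0L) stop("empty fold list", call. = FALSE)
  scores <- vapply(folds, function(f) f$mean_fg_dsc, numeric(1))
  ids <- vapply(folds, function(f) f$fold_id %||% NA_integer_, integer(1))
  best <- which(scores == max(scores))
  folds[[best[which.min(ids[best])]]]
}

# ---- elastic deformation augmentation (2D) ---------------------------

# separable reflected-border gaussian smoothing of a matrix
gauss_smooth2d <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sm_cols <- function(a) {
    n <- nrow(a)
    idx <- outer(seq_len(n), -r:r, "+")
    idx <- ifelse(idx < 1L, 2L - idx, ifelse(idx > n, 2L * n - idx, idx))
    out <- a * 0
    for (j in seq_len(2L * r + 1L))
      out <- out + a[idx[, j], , drop = FALSE] * k[j]
    out
  }
  t(sm_cols(t(sm_cols(m))))
}

# random smooth displacement field; bilinear image / nearest labels
elastic_deform2d <- function(img, lab, alpha = 6, sigma = 8) {
  d <- dim(img)
  dz <- gauss_smooth2d(matrix(stats::rnorm(prod(d)), d[1], d[2]), sigma)
  dy <- gauss_smooth2d(matrix(stats::rnorm(prod(d)), d[1], d[2]), sigma)
  dz <- alpha * dz / max(abs(dz), 1e-12)
  dy <- alpha * dy / max(abs(dy), 1e-12)
  zi <- pmin(pmax(row(img) + dz, 1), d[1])
  yi <- pmin(pmax(col(img) + dy, 1), d[2])
  z0 <- floor(zi); z1 <- pmin(z0 + 1, d[1]); fz <- zi - z0
  y0 <- floor(yi); y1 <- pmin(y0 + 1, d[2]); fy <- yi - y0
  at <- function(zz, yy) img[cbind(as.vector(zz), as.vector(yy))]
  out <- (1 - fz) * (1 - fy) * at(z0, y0) + fz * (1 - fy) * at(z1, y0) +
    (1 - fz) * fy * at(z0, y1) + fz * fy * at(z1, y1)
  dim(out) <- d
  labo <- lab[cbind(as.vector(round_half_up(zi)),
                    as.vector(round_half_up(yi)))]
  dim(labo) <- d
  list(x = out, y = labo)
}
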