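#' Block decomposition of a volume
#'
#' A `block_grid` records the common block shape, the stride, the list
#' of 1-based block corner origins (sorted lexicographically by
#' `(z, y, x)`) and the decomposition mode. Every block lies fully
#' inside the volume.
#'
#' @name block_grid
NULL

new_block_grid <- function(block_shape, stride, origins, mode, vol_dim) {
  origins <- origins[order(origins[, 1], origins[, 2], origins[, 3]), ,
                     drop = FALSE]
  structure(list(block_shape = as.integer(block_shape),
                 stride = as.integer(stride),
                 origins = origins, mode = mode,
                 vol_dim = as.integer(vol_dim)),
            class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("block_grid (%s): %d blocks of %s, stride %s, volume %s\n",
              x$mode, nrow(x$origins),
              paste(x$block_shape, collapse = "x"),
              paste(x$stride, collapse = "x"),
              paste(x$vol_dim, collapse = "x")))
  invisible(x)
}

#' Number of blocks in a grid
#' @param grid A `block_grid`.
#' @export
n_blocks <- function(grid) nrow(grid$origins)

extract_block <- function(arr, origin, shape) {
  arr[origin[1] + seq_len(shape[1]) - 1L,
      origin[2] + seq_len(shape[2]) - 1L,
      origin[3] + seq_len(shape[3]) - 1L, drop = FALSE]
}

#' Split a volume into 2D B-scan blocks
#'
#' One block per slow-axis (`x`) index, each of shape `(n_z, n_y, 1)`:
#' the standard 256 x 512 x 256 study volume yields 256 B-scan blocks of
#' 256 x 512 voxels.
#'
#' @param vol An [oct_volume()] or [label_volume()].
#' @return A `block_grid` with mode `"slices_2d"`.
#' @export
split_2d <- function(vol) {
  d <- dims_of(vol$geometry)
  origins <- cbind(1L, 1L, seq_len(d[3]))
  new_block_grid(c(d[1], d[2], 1L), c(d[1], d[2], 1L), origins,
                 "slices_2d", d)
}

#' Split a volume into disjoint 3D blocks
#'
#' Blocks span the full depth and tile the lateral plane exactly once:
#' the standard study volume with 256 x 64 x 64 blocks yields 32 blocks.
#'
#' @param vol An [oct_volume()] or [label_volume()].
#' @param block_shape `(z, y, x)` voxel counts; `z` must equal `n_z` and
#'   the lateral dims must divide the volume's.
#' @return A `block_grid` with mode `"tiles_3d_disjoint"`.
#' @export
split_3d_disjoint <- function(vol, block_shape = c(vol$geometry$n_z, 64L,
                                                   64L)) {
  d <- dims_of(vol$geometry)
  b <- as.integer(block_shape)
  if (b[1] != d[1])
    stop("block depth must equal the volume depth", call. = FALSE)
  if (d[2] %% b[2] != 0L || d[3] %% b[3] != 0L)
    stop("lateral dims must be divisible by the block dims", call. = FALSE)
  oy <- seq(1L, d[2], b[2]); ox <- seq(1L, d[3], b[3])
  origins <- cbind(1L, rep(oy, times = length(ox)),
                   rep(ox, each = length(oy)))
  new_block_grid(b, b, origins, "tiles_3d_disjoint", d)
}

#' Split a volume into overlapping 3D blocks
#'
#' Origins lie on a lateral stride lattice; the last block along each
#' lateral axis is shifted inward so that every voxel is covered at
#' least once. `stride = block dims` reduces to the disjoint tiling.
#'
#' @param vol An [oct_volume()] or [label_volume()].
#' @param block_shape `(z, y, x)`; `z` must equal `n_z`.
#' @param stride `(y, x)` lateral steps, positive and at most the block
#'   lateral dims.
#' @return A `block_grid` with mode `"tiles_3d_overlap"`.
#' @export
split_3d_overlap <- function(vol, block_shape = c(vol$geometry$n_z, 64L,
                                                  64L),
                             stride = c(32L, 32L)) {
  d <- dims_of(vol$geometry)
  b <- as.integer(block_shape)
  s <- as.integer(stride)
  if (b[1] != d[1])
    stop("block depth must equal the volume depth", call. = FALSE)
  if (any(s <= 0L)) stop("stride must be positive", call. = FALSE)
  if (s[1] > b[2] || s[2] > b[3])
    stop("stride must not exceed the block lateral dims", call. = FALSE)
  if (b[2] > d[2] || b[3] > d[3])
    stop("block larger than volume", call. = FALSE)
  lattice <- function(n, bl, st) {
    o <- seq(1L, max(1L, n - bl + 1L), st)
    if (o[length(o)] + bl - 1L < n) o <- c(o, n - bl + 1L)
    unique(o)
  }
  oy <- lattice(d[2], b[2], s[1]); ox <- lattice(d[3], b[3], s[2])
  origins <- cbind(1L, rep(oy, times = length(ox)),
                   rep(ox, each = length(oy)))
  new_block_grid(b, c(d[1], s), origins, "tiles_3d_overlap", d)
}

#' How many blocks cover each voxel
#' @param grid A `block_grid`.
#' @return Integer array of the volume's shape.
#' @export
coverage_count <- function(grid) {
  cov <- array(0L, grid$vol_dim)
  b <- grid$block_shape
  for (k in seq_len(nrow(grid$origins))) {
    o <- grid$origins[k, ]
    cov[o[1] + seq_len(b[1]) - 1L, o[2] + seq_len(b[2]) - 1L,
        o[3] + seq_len(b[3]) - 1L] <-
      cov[o[1] + seq_len(b[1]) - 1L, o[2] + seq_len(b[2]) - 1L,
          o[3] + seq_len(b[3]) - 1L] + 1L
  }
  cov
}

#' Blending parameters for overlapping-block inference
#'
#' @param sigma_vox Gaussian radius in voxels (default 16).
#' @param distance `"lateral"` (default; blocks span the full depth so
#'   overlap is lateral-only) or `"full3d"`.
#' @return An object of class `blend_params`.
#' @export
blend_params <- function(sigma_vox = 16, distance = c("lateral", "full3d")) {
  if (sigma_vox <= 0) stop("sigma_vox must be > 0", call. = FALSE)
  structure(list(sigma_vox = sigma_vox, distance = match.arg(distance)),
            class = "blend_params")
}

#' Gaussian blending weight of a voxel within a block
#'
#' `w = exp(-d^2 / (2 sigma^2))` with `d` the Euclidean distance from
#' the voxel to the block centre in the configured subspace.
#'
#' @param voxel `(z, y, x)` voxel index (1-based).
#' @param origin Block corner `(z, y, x)`.
#' @param block_shape Block shape `(z, y, x)`.
#' @param params A [blend_params()].
#' @return Weight in (0, 1].
#' @export
gaussian_weight <- function(voxel, origin, block_shape,
                            params = blend_params()) {
  voxel <- as.numeric(voxel); origin <- as.numeric(origin)
  if (any(voxel < origin) || any(voxel > origin + block_shape - 1))
    stop("voxel outside block", call. = FALSE)
  ctr <- origin + (as.numeric(block_shape) - 1) / 2
  dlt <- voxel - ctr
  if (params$distance == "lateral") dlt <- dlt[2:3]
  exp(-sum(dlt^2) / (2 * params$sigma_vox^2))
}

# lateral Gaussian weight map of one block (matrix n_by x n_bx)
block_weight_map <- function(block_shape, params) {
  cy <- (block_shape[2] + 1) / 2; cx <- (block_shape[3] + 1) / 2
  wy <- exp(-(seq_len(block_shape[2]) - cy)^2 / (2 * params$sigma_vox^2))
  wx <- exp(-(seq_len(block_shape[3]) - cx)^2 / (2 * params$sigma_vox^2))
  outer(wy, wx)
}

#' Segment a volume by per-block inference with Gaussian blending
#'
#' Runs the network on every block of the grid; for voxels covered by
#' several overlapping blocks, per-class confidences (softmax-normalized
#' per block by default, so values are comparable across blocks) are
#' averaged with Gaussian weights centred on each block
#' (`w = exp(-d^2/(2 sigma^2))`, lateral distance), then each voxel is
#' assigned the class with the highest blended confidence (ties toward
#' the lowest class index). For `slices_2d` grids the blocks are
#' disjoint and blending degenerates to direct assembly.
#'
#' @param vol An [oct_volume()].
#' @param net A [unet()] whose dimensionality matches the grid mode.
#' @param grid A `block_grid` covering the volume.
#' @param params A [blend_params()].
#' @param normalize_scores Softmax per-block scores before weighting
#'   (default TRUE; FALSE blends raw scores).
#' @param preprocess Optional function applied to the whole intensity
#'   array before splitting (e.g. intensity normalization).
#' @return A [label_volume()].
#' @export
blend_predict <- function(vol, net, grid, params = blend_params(),
                          normalize_scores = TRUE, preprocess = NULL) {
  if (!is.null(preprocess)) {
    arr <- preprocess(vol$intensity)
    stopifnot(identical(dim(arr), dim(vol$intensity)))
    vol$intensity <- arr
  }
  score_fun <- function(block) {
    x <- if (net$config$dims == 2L) {
      array(block, dim(block)[1:2])
    } else block
    sc <- unet_forward(net, x, train = FALSE)$scores
    d <- dim(sc)
    m <- matrix(sc, ncol = d[length(d)])
    if (normalize_scores) m <- softmax_scores(m)
    m  # (voxels of block, K), voxel order = column-major (z, y, x)
  }
  blend_scores(vol, grid, score_fun, params, net$config$n_classes)
}

# Shared blending engine; score_fun(block_array) must return a
# (n_block_voxels x K) matrix in the block's column-major voxel order.
# return_conf additionally returns the blended per-class confidences.
blend_scores <- function(vol, grid, score_fun, params, n_classes,
                         return_conf = FALSE) {
  d <- dims_of(vol$geometry)
  b <- grid$block_shape
  acc <- array(0, c(d, n_classes))
  wacc <- array(0, d)
  wmap <- block_weight_map(b, params)
  wblk <- rep(wmap, each = b[1])        # expand over depth
  for (k in seq_len(nrow(grid$origins))) {
    o <- grid$origins[k, ]
    iz <- o[1] + seq_len(b[1]) - 1L
    iy <- o[2] + seq_len(b[2]) - 1L
    ix <- o[3] + seq_len(b[3]) - 1L
    blk <- vol$intensity[iz, iy, ix, drop = FALSE]
    sc <- score_fun(blk)
    for (cl in seq_len(n_classes)) {
      v <- sc[, cl] * wblk
      prev <- acc[iz, iy, ix, cl, drop = FALSE]
      dim(v) <- dim(prev)
      acc[iz, iy, ix, cl] <- prev + v
    }
    prevw <- wacc[iz, iy, ix, drop = FALSE]
    wacc[iz, iy, ix] <- prevw + array(wblk, dim(prevw))
  }
  if (any(wacc == 0))
    stop("internal error: grid does not cover the volume", call. = FALSE)
  conf <- matrix(acc, ncol = n_classes) / as.vector(wacc)
  lab <- max.col(conf, ties.method = "first")
  lab <- array(as.integer(lab), d)
  out <- label_volume(lab, vol$geometry)
  if (return_conf) list(labels = out, conf = array(conf, c(d, n_classes)))
  else out
}
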