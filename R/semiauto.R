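#' Cuboid region of interest inside one layer
#'
#' A cuboid `M_i` selected so that every voxel is guaranteed to belong to
#' layer `i` (no boundary voxels); its intensity statistics drive the
#' layer's detection threshold. Bounds are 1-based and inclusive.
#'
#' @param layer Class index in 2..5.
#' @param z0,z1,y0,y1,x0,x1 Inclusive voxel bounds.
#' @return An object of class `layer_roi`.
#' @export
layer_roi <- function(layer, z0, z1, y0, y1, x0, x1) {
  layer <- as.integer(layer)
  if (!(layer %in% 2:5)) stop("layer must be in 2..5", call. = FALSE)
  b <- as.integer(c(z0, z1, y0, y1, x0, x1))
  if (any(is.na(b)) || b[1] > b[2] || b[3] > b[4] || b[5] > b[6] ||
      any(b < 1L))
    stop("ROI bounds must be 1-based with lo <= hi", call. = FALSE)
  structure(list(layer = layer, z0 = b[1], z1 = b[2], y0 = b[3],
                 y1 = b[4], x0 = b[5], x1 = b[6]),
            class = "layer_roi")
}

roi_values <- function(vol, roi) {
  d <- dim(vol$intensity)
  if (roi$z1 > d[1] || roi$y1 > d[2] || roi$x1 > d[3])
    stop("ROI exceeds volume bounds", call. = FALSE)
  vol$intensity[roi$z0:roi$z1, roi$y0:roi$y1, roi$x0:roi$x1]
}

#' Parameters of the semi-automatic labeler
#'
#' One threshold multiplier `alpha`, one surface-median window `w` and
#' one crossing direction per layer 2..5, plus the size of the 3D median
#' window applied below each found boundary to suppress speckle.
#'
#' The default crossing sequence (rising, falling, rising, falling)
#' follows the bright/dark/bright/dark contrast of thick skin: the probe
#' gap is dark, the upper stratum corneum bright, the ordered stratum
#' corneum darker, the cellular epidermis brighter again and the dermis
#' dimmer. Default `alpha` values were calibrated once on the default
#' phantom contrast and attenuation.
#'
#' @param alpha Numeric length-4 vector (layers 2..5) of threshold
#'   multipliers; the threshold is `mean(ROI) - alpha * sd(ROI)` and
#'   `alpha` may be negative to place the threshold above the ROI mean.
#' @param w Odd surface-median window sizes, length 4 (default 11).
#' @param crossing Character length-4, each `"rising"` or `"falling"`.
#' @param despeckle_window Odd 3D median window applied below each found
#'   boundary (default 3). 1 disables despeckling.
#' @return An object of class `semiauto_params`.
#' @export
semiauto_params <- function(alpha = c(1.5, -1.5, 1.0, -3),
                            w = rep(11L, 4L),
                            crossing = c("rising", "falling", "rising",
                                         "falling"),
                            despeckle_window = 3L) {
  w <- as.integer(rep_len(w, 4L))
  alpha <- as.numeric(rep_len(alpha, 4L))
  crossing <- rep_len(crossing, 4L)
  if (any(w < 1L) || any(w %% 2L == 0L))
    stop("surface-median windows w must be odd and >= 1", call. = FALSE)
  despeckle_window <- as.integer(despeckle_window)
  if (despeckle_window < 1L || despeckle_window %% 2L == 0L)
    stop("despeckle_window must be odd and >= 1", call. = FALSE)
  if (!all(crossing %in% c("rising", "falling")))
    stop("crossing entries must be 'rising' or 'falling'", call. = FALSE)
  structure(list(alpha = alpha, w = w, crossing = crossing,
                 despeckle_window = despeckle_window),
            class = "semiauto_params")
}

#' Detection threshold from ROI statistics
#'
#' `I_t = mean(ROI) - alpha * sd(ROI)` with the population (divide-by-n)
#' standard deviation. `alpha` is the layer's empirically selected
#' multiplier; negative values place the threshold above the mean.
#'
#' @param vol An [oct_volume()].
#' @param roi A [layer_roi()] inside the layer.
#' @param alpha Dimensionless multiplier.
#' @return Threshold intensity (scalar).
#' @export
layer_threshold <- function(vol, roi, alpha) {
  v <- roi_values(vol, roi)
  if (length(v) == 0L) stop("empty ROI", call. = FALSE)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  m - alpha * s
}

#' Detect the upper boundary surface of a layer
#'
#' For every lateral column, scans downward in depth from `z_start`
#' (default: the top of the volume) and returns the first depth where the
#' intensity reaches the threshold: `>=` for a `rising` crossing into a
#' brighter layer, `<=` for a `falling` crossing into a darker one.
#' Columns with no crossing are assigned the deepest scanned index and
#' flagged.
#'
#' @param vol An [oct_volume()].
#' @param threshold Intensity threshold (see [layer_threshold()]).
#' @param crossing `"rising"` or `"falling"`.
#' @param layer Class index the surface belongs to (for bookkeeping).
#' @param z_start Integer matrix `(n_y, n_x)` of first depths to scan, a
#'   single integer, or `NULL` for the top of the volume.
#' @return A [boundary_surface()] with a `flagged` matrix (`TRUE` where
#'   no crossing was found).
#' @export
detect_upper_boundary <- function(vol, threshold,
                                  crossing = c("rising", "falling"),
                                  layer = 2L, z_start = NULL) {
  crossing <- match.arg(crossing)
  d <- dim(vol$intensity)
  if (is.null(z_start)) z_start <- 1L
  if (!is.matrix(z_start)) z_start <- matrix(as.integer(z_start), d[2], d[3])
  if (any(z_start > d[1]) || any(z_start < 1L))
    stop("z_start outside the grid", call. = FALSE)
  storage.mode(z_start) <- "integer"
  res <- cpp_first_crossing(vol$intensity, dim(vol$intensity),
                            threshold, crossing == "rising", z_start)
  boundary_surface(layer, res$z + 0.0, d[1], flagged = !res$found)
}

#' Median-smooth a boundary surface
#'
#' Applies a 2D median filter with a `w x w` lateral window to the
#' surface's depth coordinate; borders are handled by reflection and the
#' output is clamped to the grid.
#'
#' @param surface A [boundary_surface()].
#' @param w Odd window size (default 11).
#' @param n_z Grid depth for clamping (optional).
#' @return The smoothed [boundary_surface()].
#' @export
smooth_surface <- function(surface, w = 11L, n_z = NULL) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("w must be odd and >= 1", call. = FALSE)
  z <- if (w == 1L) surface$z else cpp_median2d(surface$z, w)
  if (!is.null(n_z)) z <- pmin(pmax(z, 1), n_z)
  boundary_surface(surface$layer, z, n_z, flagged = surface$flagged)
}

#' Despeckle the volume below a boundary surface
#'
#' 3D median filter (cubic window, borders clipped) applied only to
#' voxels at or below the surface; voxels above it are untouched.
#'
#' @param vol An [oct_volume()].
#' @param surface A [boundary_surface()].
#' @param window Odd window size (default 3); 1 is a no-op.
#' @return The filtered [oct_volume()].
#' @export
despeckle_below <- function(vol, surface, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  if (window == 1L) return(vol)
  zs <- round_half_up(surface$z)
  out <- cpp_median3d_below(vol$intensity, dim(vol$intensity), zs, window)
  dim(out) <- dim(vol$intensity)
  oct_volume(out, vol$geometry, id = vol$id)
}

#' Semi-automatic primary segmentation
#'
#' Iterates over layers i = 2..5: compute the layer's threshold from its
#' ROI statistics, detect the upper boundary scanning strictly below the
#' previous layer's smoothed surface, median-smooth the surface, clamp it
#' to lie at or below the previous one, then median-filter the volume
#' below the boundary to reduce speckle before the next layer is
#' processed. Labels are finally assigned per column: class 1 above the
#' layer-2 surface, class i between consecutive surfaces, class 5 to the
#' bottom.
#'
#' @param vol An [oct_volume()].
#' @param rois List of four [layer_roi()] objects, one per layer 2..5.
#' @param params A [semiauto_params()].
#' @return List with `labels` (a [label_volume()]) and `boundaries`
#'   (list of four smoothed [boundary_surface()]s).
#' @export
run_semiauto <- function(vol, rois, params = semiauto_params()) {
  stopifnot(inherits(params, "semiauto_params"))
  layers <- vapply(rois, function(r) r$layer, integer(1))
  if (!identical(sort(layers), 2:5))
    stop("need exactly one ROI per layer 2..5", call. = FALSE)
  rois <- rois[order(layers)]
  d <- dim(vol$intensity)
  work <- vol
  surfaces <- vector("list", 4L)
  prev <- NULL
  for (k in 1:4) {
    thr <- layer_threshold(work, rois[[k]], params$alpha[k])
    z_start <- if (is.null(prev)) 1L else
      matrix(pmin(as.integer(round_half_up(prev$z)) + 1L, d[1]), d[2], d[3])
    s <- detect_upper_boundary(work, thr, params$crossing[k],
                               layer = k + 1L, z_start = z_start)
    s <- smooth_surface(s, params$w[k], n_z = d[1])
    if (!is.null(prev)) s$z <- pmax(s$z, prev$z)
    work <- despeckle_below(work, s, params$despeckle_window)
    surfaces[[k]] <- s
    prev <- s
  }
  list(labels = labels_from_surfaces(surfaces, vol$geometry),
       boundaries = surfaces)
}

#' Propose safe per-layer ROIs from a label volume
#'
#' Picks, for each layer 2..5, a central lateral patch and the depth
#' band that belongs to the layer in every column of the patch, shrunk
#' by a margin — a cuboid guaranteed inside the layer, as an expert
#' would select.
#'
#' @param truth A [label_volume()].
#' @param margin Depth margin in voxels kept clear of both boundaries.
#' @param lateral_frac Fraction of the lateral field used, centred.
#' @return List of four [layer_roi()] objects (layers 2..5).
#' @export
label_rois <- function(truth, margin = 2L, lateral_frac = 0.25) {
  stopifnot(inherits(truth, "label_volume"))
  g <- truth$geometry
  ctr <- function(n) {
    k <- max(1L, as.integer(round(n * lateral_frac)))
    lo <- (n - k) %/% 2L + 1L
    c(lo, lo + k - 1L)
  }
  yy <- ctr(g$n_y); xx <- ctr(g$n_x)
  sub <- truth$labels[, yy[1]:yy[2], xx[1]:xx[2], drop = FALSE]
  lapply(2:5, function(cl) {
    is_cl <- sub == cl
    all_cl <- apply(is_cl, 1, all)     # depths where every column is cl
    zs <- which(all_cl)
    if (length(zs) == 0L)
      stop("no depth band lies entirely inside layer ", cl, call. = FALSE)
    z0 <- min(zs) + margin; z1 <- max(zs) - margin
    if (z1 < z0) { z0 <- zs[ceiling(length(zs) / 2)]; z1 <- z0 }
    layer_roi(cl, z0, z1, yy[1], yy[2], xx[1], xx[2])
  })
}

#' Propose safe per-layer ROIs from planted phantom boundaries
#'
#' Stand-in for the expert's manual ROI selection when labeling phantom
#' data: picks, for each layer, a central lateral patch and the depth
#' band strictly inside the layer (margin voxels away from both
#' boundaries).
#'
#' @param phantom An `oct_phantom`.
#' @param margin Depth margin in voxels kept clear of both boundaries.
#' @param lateral_frac Fraction of the lateral field used, centred.
#' @return List of four [layer_roi()] objects (layers 2..5).
#' @export
phantom_rois <- function(phantom, margin = 2L, lateral_frac = 0.25) {
  g <- phantom$params$geometry
  b <- phantom$boundaries
  ctr <- function(n) {
    k <- max(1L, as.integer(round(n * lateral_frac)))
    lo <- (n - k) %/% 2L + 1L
    c(lo, lo + k - 1L)
  }
  yy <- ctr(g$n_y); xx <- ctr(g$n_x)
  zs <- lapply(b, function(s) round_half_up(s$z[yy[1]:yy[2], xx[1]:xx[2]]))
  lapply(1:4, function(k) {
    z0 <- max(zs[[k]]) + margin
    z1 <- if (k < 4) min(zs[[k + 1]]) - 1L - margin else
      min(g$n_z, max(zs[[4]]) + margin + 10L)
    if (z1 < z0) { z0 <- max(zs[[k]]); z1 <- z0 }  # very thin layer
    layer_roi(k + 1L, z0, min(z1, g$n_z), yy[1], yy[2], xx[1], xx[2])
  })
}
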