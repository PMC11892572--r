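#' Voxel geometry of an OCT volume
#'
#' Describes the voxel grid and physical extent of a 3D OCT volume. The
#' depth axis (`z`) measures optical path length, so the physical depth
#' extent is an *optical* extent; conversion to geometric (tissue)
#' distances divides by the tissue refractive index.
#'
#' The package's axis convention, used everywhere, is `(z, y, x)`:
#' `z` = depth (first, fastest-varying array index), `y` = lateral fast
#' axis (along a B-scan), `x` = lateral slow axis (across B-scans).
#'
#' @param n_z,n_y,n_x Voxel counts along depth and the two lateral axes.
#' @param extent_z_mm,extent_y_mm,extent_x_mm Physical extents in mm
#'   (`extent_z_mm` is optical path length). Defaults match a full-field
#'   acquisition of 256 x 512 x 512 voxels over 1.2 x 3.0 x 3.0 mm.
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry()
#' delta_z_opt_um(g)  # 4.6875 um optical depth per voxel
#' @export
voxel_geometry <- function(n_z = 256L, n_y = 512L, n_x = 512L,
                           extent_z_mm = 1.2, extent_y_mm = 3.0,
                           extent_x_mm = 3.0) {
  n_z <- as.integer(n_z); n_y <- as.integer(n_y); n_x <- as.integer(n_x)
  if (any(c(n_z, n_y, n_x) < 1L))
    stop("voxel counts must be >= 1", call. = FALSE)
  if (any(!is.finite(c(extent_z_mm, extent_y_mm, extent_x_mm))) ||
      any(c(extent_z_mm, extent_y_mm, extent_x_mm) <= 0))
    stop("physical extents must be positive and finite", call. = FALSE)
  structure(list(n_z = n_z, n_y = n_y, n_x = n_x,
                 extent_z_mm = extent_z_mm, extent_y_mm = extent_y_mm,
                 extent_x_mm = extent_x_mm),
            class = "voxel_geometry")
}

#' @return `delta_z_opt_um()`: optical depth per voxel in micrometres.
#' @rdname voxel_geometry
#' @param geometry A `voxel_geometry`.
#' @export
delta_z_opt_um <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  1000 * geometry$extent_z_mm / geometry$n_z
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g mm\n",
              x$n_z, x$n_y, x$n_x,
              x$extent_z_mm, x$extent_y_mm, x$extent_x_mm))
  invisible(x)
}

dims_of <- function(geometry) c(geometry$n_z, geometry$n_y, geometry$n_x)

#' OCT intensity volume
#'
#' A 3D grid of non-negative OCT signal intensities (relative units)
#' indexed `(z, y, x)` together with its physical geometry.
#'
#' @param intensity Numeric 3D array, shape `(n_z, n_y, n_x)`, finite and
#'   non-negative.
#' @param geometry A [voxel_geometry()] matching the array shape.
#' @param id Free-text source label.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, geometry = NULL, id = "volume") {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3D array", call. = FALSE)
  d <- dim(intensity)
  if (is.null(geometry))
    geometry <- voxel_geometry(d[1], d[2], d[3],
                               1.2, 3.0 * d[2] / 512, 3.0 * d[3] / 512)
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!identical(d, dims_of(geometry)))
    stop("intensity shape does not match geometry", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity values must be finite and >= 0", call. = FALSE)
  structure(list(intensity = intensity, geometry = geometry,
                 id = as.character(id)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume '%s': %d x %d x %d voxels (z,y,x), range [%.3g, %.3g]\n",
              x$id, d[1], d[2], d[3], min(x$intensity), max(x$intensity)))
  print(x$geometry)
  invisible(x)
}

#' Names of the five structural classes
#'
#' Class 1 is the probe-gap space above the skin surface; classes 2-5 are
#' the structural skin layers in depth order.
#' @return Named character vector of length 5.
#' @export
oct_class_names <- function() {
  c(`1` = "background", `2` = "upper_sc", `3` = "ordered_sc",
    `4` = "epidermis", `5` = "dermis")
}

#' Five-class label volume
#'
#' Integer class labels on the same `(z, y, x)` grid as an intensity
#' volume. Valid class values are 1..5 (see [oct_class_names()]); along
#' each lateral column the class index is non-decreasing with depth
#' because the skin layers are stacked.
#'
#' @param labels Integer 3D array with values in 1..5.
#' @param geometry A [voxel_geometry()] matching the array shape.
#' @param check_monotone Verify the per-column depth-monotonicity
#'   invariant (costs one pass over the volume).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, geometry = NULL, check_monotone = FALSE) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  d <- dim(labels)
  if (is.null(geometry))
    geometry <- voxel_geometry(d[1], d[2], d[3],
                               1.2, 3.0 * d[2] / 512, 3.0 * d[3] / 512)
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!identical(d, dims_of(geometry)))
    stop("label shape does not match geometry", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 1L) || any(labels > 5L))
    stop("labels must be integers in 1..5", call. = FALSE)
  if (check_monotone && !labels_monotone(labels))
    stop("labels are not depth-monotone along every column", call. = FALSE)
  structure(list(labels = labels, geometry = geometry,
                 class_names = oct_class_names()),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(x$labels, 5L)
  cat(sprintf("label_volume: %d x %d x %d voxels (z,y,x)\n", d[1], d[2], d[3]))
  cat("  voxels per class:",
      paste(sprintf("%s=%d", x$class_names, tab), collapse = ", "), "\n")
  invisible(x)
}

# TRUE when class indices never decrease with depth in any lateral column
labels_monotone <- function(labels) {
  d <- dim(labels)
  if (d[1] < 2L) return(TRUE)
  !any(labels[-1L, , , drop = FALSE] < labels[-d[1], , , drop = FALSE])
}

#' Upper-boundary surface of a layer
#'
#' Depth index of the first voxel of a layer for every lateral column
#' `(y, x)`. Depths may be real-valued (sub-voxel) before rounding;
#' label assignment rounds half-up to voxel indices.
#'
#' @param layer Class index in 2..5.
#' @param z Numeric matrix `(n_y, n_x)` of 1-based depth indices.
#' @param n_z Depth of the parent grid (for validation), or `NULL`.
#' @param flagged Optional logical matrix marking columns where detection
#'   found no crossing.
#' @return An object of class `boundary_surface`.
#' @export
boundary_surface <- function(layer, z, n_z = NULL, flagged = NULL) {
  layer <- as.integer(layer)
  if (!(layer %in% 2:5)) stop("layer must be in 2..5", call. = FALSE)
  if (!is.matrix(z)) stop("z must be a matrix (n_y, n_x)", call. = FALSE)
  if (!is.null(n_z) && (any(z < 1) || any(z > n_z)))
    stop("surface depths outside grid", call. = FALSE)
  structure(list(layer = layer, z = z, flagged = flagged),
            class = "boundary_surface")
}

#' @export
print.boundary_surface <- function(x, ...) {
  cat(sprintf("boundary_surface of layer %d: %d x %d columns, depth range [%.2f, %.2f]\n",
              x$layer, nrow(x$z), ncol(x$z), min(x$z), max(x$z)))
  invisible(x)
}

# round half-up (R's round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Build a label volume from ordered boundary surfaces
#'
#' Assigns, per lateral column, class 1 above the layer-2 surface, class
#' i on depths `[z_i, z_{i+1})` and class 5 from its surface to the grid
#' bottom. Surfaces are rounded half-up to integer voxel indices.
#'
#' @param surfaces List of four [boundary_surface()] objects for layers
#'   2, 3, 4, 5 (in order, ordered in depth).
#' @param geometry Grid [voxel_geometry()].
#' @return A [label_volume()].
#' @export
labels_from_surfaces <- function(surfaces, geometry) {
  stopifnot(length(surfaces) == 4L)
  d <- dims_of(geometry)
  lab <- array(1L, d)
  zidx <- rep(seq_len(d[1]), times = d[2] * d[3])
  for (s in surfaces) {
    zs <- round_half_up(s$z)
    # expand surface to the full grid: columns vary slowest
    lab <- lab + as.integer(zidx >= rep(as.vector(zs), each = d[1]))
  }
  dim(lab) <- d
  lab[lab > 5L] <- 5L
  label_volume(lab, geometry)
}
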