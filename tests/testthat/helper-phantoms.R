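# Shared fixtures, built in code.

# small grid that keeps the optical voxel depth of the full-field
# acquisition (1.2 mm / 256 = 4.6875 um)
small_geom <- function(n_z = 64L, n_y = 64L, n_x = 32L) {
  voxel_geometry(n_z, n_y, n_x,
                 extent_z_mm = 1.2 * n_z / 256,
                 extent_y_mm = 3.0 * n_y / 512,
                 extent_x_mm = 3.0 * n_x / 512)
}

# phantom params that fit a 64-voxel-deep grid
small_params <- function(geometry = small_geom(), seed = 1L,
                         gap_depth_vox = 6,
                         layer_thickness_um = c(`2` = 15, `3` = 60,
                                                `4` = 55),
                         undulation_amplitude_vox = 2,
                         undulation_period_vox = 20,
                         tilt_amplitude_vox = 1, ...) {
  phantom_params(geometry = geometry,
                 gap_depth_vox = gap_depth_vox,
                 layer_thickness_um = layer_thickness_um,
                 undulation_amplitude_vox = undulation_amplitude_vox,
                 undulation_period_vox = undulation_period_vox,
                 tilt_amplitude_vox = tilt_amplitude_vox,
                 seed = seed, ...)
}

# thresholds that separate adjacent layers exactly on a noise-free
# phantom, expressed as the alpha multipliers of the labeler: mirrors
# the expert's per-volume parameter selection deterministically
calibrated_alphas <- function(phantom) {
  vol <- phantom$volume
  lab <- phantom$truth$labels
  I <- vol$intensity
  rois <- phantom_rois(phantom)
  crossing <- c("rising", "falling", "rising", "falling")
  vapply(1:4, function(k) {
    i <- k + 1
    target <- if (crossing[k] == "rising")
      (max(I[lab == i - 1]) + min(I[lab == i])) / 2
    else
      (min(I[lab == i - 1]) + max(I[lab == i])) / 2
    m <- layer_threshold(vol, rois[[k]], 0)
    s <- m - layer_threshold(vol, rois[[k]], 1)
    (m - target) / s
  }, numeric(1))
}

# brute-force sliding-window median of a depth map (oracle for
# smooth_surface), reflecting borders
brute_median2d <- function(z, w) {
  h <- w %/% 2
  ny <- nrow(z); nx <- ncol(z)
  # edge-inclusive reflection: ...cba|abc...
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  out <- z
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    yy <- refl(y + (-h:h), ny)
    xx <- refl(x + (-h:h), nx)
    out[y, x] <- stats::median(z[yy, xx])
  }
  out
}

# brute-force per-class DSC by explicit counting (oracle for dice)
brute_dice <- function(t, s) {
  vapply(1:5, function(i) {
    nt <- sum(t == i); ns <- sum(s == i); nm <- sum(t == i & s == i)
    if (nt + ns == 0) 1 else 2 * nm / (nt + ns)
  }, numeric(1))
}
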