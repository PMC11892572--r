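#' Parameters of the layered thick-skin speckle phantom
#'
#' The phantom emulates the stereotypical OCT appearance of human thick
#' skin: a dark probe-gap background (class 1), a thin bright upper
#' stratum corneum (2), a thick darker ordered stratum corneum (3), a
#' brighter cellular epidermis (4) and a dimmer dermis (5) filling the
#' remaining depth (its lower border is beyond the imaging depth).
#' Boundaries of layers 4 and 5 undulate sinusoidally to mimic papillary
#' patterns; intensity decays exponentially with optical depth below the
#' tissue surface; multiplicative unit-mean gamma speckle is applied.
#'
#' Layer thicknesses are *geometric* (tissue) thicknesses in micrometres;
#' their optical extent on the depth axis is `thickness * refractive_index`.
#'
#' @param geometry Grid [voxel_geometry()].
#' @param gap_depth_vox Mean depth of the probe-gap background, voxels.
#' @param layer_thickness_um Named numeric vector with entries `"2"`,
#'   `"3"`, `"4"`: mean geometric thickness of the upper stratum corneum,
#'   ordered stratum corneum and cellular epidermis. Defaults 20, 153 and
#'   137 um (cohort means for thick finger-pad skin).
#' @param thickness_jitter_frac Relative SD of the per-volume thickness
#'   draw in [make_dataset()].
#' @param refractive_index Average tissue refractive index (default 1.4).
#' @param layer_mean_intensity Mean signal per class 1..5, relative
#'   units; must respect the thick-skin contrast ordering
#'   `I2 > I4 > I3`, `I4 > I5`, `I1 < I3`.
#' @param attenuation_per_mm Exponential decay coefficient applied to
#'   tissue classes as a function of optical depth below the skin
#'   surface, 1/mm.
#' @param undulation_amplitude_vox,undulation_period_vox Amplitude and
#'   lateral period (voxels) of the sinusoidal papillary undulation of
#'   the epidermis boundaries (layers 4 and 5).
#' @param tilt_amplitude_vox Maximum smooth random tilt of the skin
#'   surface across the field, voxels.
#' @param speckle_shape Shape of the unit-mean multiplicative gamma
#'   speckle; speckle contrast is `1/sqrt(speckle_shape)`. `Inf` turns
#'   speckle off.
#' @param seed RNG seed making the phantom reproducible.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(geometry = voxel_geometry(),
                           gap_depth_vox = 15,
                           layer_thickness_um = c(`2` = 20, `3` = 153,
                                                  `4` = 137),
                           thickness_jitter_frac = 0.1,
                           refractive_index = 1.4,
                           layer_mean_intensity = c(`1` = 5, `2` = 100,
                                                    `3` = 40, `4` = 70,
                                                    `5` = 30),
                           attenuation_per_mm = 1.0,
                           undulation_amplitude_vox = 3,
                           undulation_period_vox = 40,
                           tilt_amplitude_vox = 2,
                           speckle_shape = 4,
                           seed = 1L) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  lt <- layer_thickness_um[c("2", "3", "4")]
  if (anyNA(lt) || any(lt <= 0))
    stop("layer_thickness_um must give positive thicknesses for layers 2..4",
         call. = FALSE)
  I <- layer_mean_intensity[as.character(1:5)]
  if (anyNA(I)) stop("layer_mean_intensity must cover classes 1..5",
                     call. = FALSE)
  if (!(I[["2"]] > I[["4"]] && I[["4"]] > I[["3"]] && I[["4"]] > I[["5"]] &&
        I[["1"]] < I[["3"]]))
    stop("intensity ordering must satisfy I2 > I4 > I3, I4 > I5, I1 < I3",
         call. = FALSE)
  if (speckle_shape <= 0) stop("speckle_shape must be > 0", call. = FALSE)
  if (undulation_amplitude_vox < 0 || undulation_period_vox <= 0)
    stop("undulation amplitude must be >= 0 and period > 0", call. = FALSE)
  if (thickness_jitter_frac < 0)
    stop("thickness_jitter_frac must be >= 0", call. = FALSE)
  dz <- delta_z_opt_um(geometry)
  opt_vox <- sum(lt) * refractive_index / dz
  if (gap_depth_vox + opt_vox >= geometry$n_z)
    stop("gap depth plus optical layer thicknesses exceed the grid depth",
         call. = FALSE)
  structure(list(geometry = geometry, gap_depth_vox = gap_depth_vox,
                 layer_thickness_um = lt,
                 thickness_jitter_frac = thickness_jitter_frac,
                 refractive_index = refractive_index,
                 layer_mean_intensity = I,
                 attenuation_per_mm = attenuation_per_mm,
                 undulation_amplitude_vox = undulation_amplitude_vox,
                 undulation_period_vox = undulation_period_vox,
                 tilt_amplitude_vox = tilt_amplitude_vox,
                 speckle_shape = speckle_shape,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# optical thickness of a layer in voxels
optical_vox <- function(params, layer) {
  params$layer_thickness_um[[as.character(layer)]] *
    params$refractive_index / delta_z_opt_um(params$geometry)
}

# smooth random tilt plane with zero mean, slopes bounded by amp
random_tilt <- function(n_y, n_x, amp) {
  ay <- stats::runif(1, -amp, amp) / max(n_y - 1, 1)
  ax <- stats::runif(1, -amp, amp) / max(n_x - 1, 1)
  yy <- seq_len(n_y) - (n_y + 1) / 2
  xx <- seq_len(n_x) - (n_x + 1) / 2
  outer(yy, xx, function(y, x) ay * y + ax * x)
}

# sinusoidal papillary bump field with random phases
undulation_field <- function(n_y, n_x, amp, period) {
  if (amp == 0) return(matrix(0, n_y, n_x))
  p1 <- stats::runif(1, 0, 2 * pi)
  p2 <- stats::runif(1, 0, 2 * pi)
  outer(seq_len(n_y), seq_len(n_x), function(y, x)
    amp * sin(2 * pi * y / period + p1) * sin(2 * pi * x / period + p2))
}

#' Sample the four layer boundary surfaces of a phantom
#'
#' Surfaces of layers 2 and 3 are smooth (random tilt only); the
#' epidermis boundaries (layers 4 and 5) additionally carry a sinusoidal
#' papillary undulation with random phase. Consecutive surfaces are
#' separated, in expectation, by the layer's optical thickness in voxels
#' (`thickness_um * refractive_index / delta_z_opt_um`), and each surface
#' is clamped to lie at or below the one above.
#'
#' Uses the current RNG state; seed management is the caller's job
#' ([render_phantom()] seeds from `params$seed`).
#'
#' @param params A [phantom_params()].
#' @return List of four [boundary_surface()] objects (layers 2..5).
#' @export
sample_boundaries <- function(params) {
  g <- params$geometry
  amp <- params$undulation_amplitude_vox
  per <- params$undulation_period_vox
  tilt <- random_tilt(g$n_y, g$n_x, params$tilt_amplitude_vox)
  z2 <- params$gap_depth_vox + 1 + tilt
  z3 <- z2 + optical_vox(params, 2)
  z4 <- z3 + optical_vox(params, 3) + undulation_field(g$n_y, g$n_x, amp, per)
  z5 <- z4 + optical_vox(params, 4) + undulation_field(g$n_y, g$n_x, amp, per)
  z3 <- pmax(z3, z2); z4 <- pmax(z4, z3); z5 <- pmax(z5, z4)
  if (max(z5) >= g$n_z)
    stop("boundary surfaces extend past the bottom of the grid",
         call. = FALSE)
  if (min(z2) < 1)
    stop("skin surface extends above the top of the grid", call. = FALSE)
  list(boundary_surface(2L, z2, g$n_z), boundary_surface(3L, z3, g$n_z),
       boundary_surface(4L, z4, g$n_z), boundary_surface(5L, z5, g$n_z))
}

#' Render a seeded speckle phantom
#'
#' The noise-free image is the per-class mean intensity attenuated by
#' `exp(-attenuation_per_mm * optical depth below the skin surface)`
#' (the probe gap, class 1, is not attenuated); the final image
#' multiplies it by i.i.d. unit-mean gamma speckle. Ground-truth labels
#' are assigned from the sampled boundary surfaces, so truth and
#' boundaries are mutually consistent by construction. Deterministic
#' given `params$seed`.
#'
#' @param params A [phantom_params()].
#' @param noise Apply speckle (default `TRUE`; `FALSE` gives the
#'   attenuated piecewise-constant field).
#' @return An object of class `oct_phantom` with fields `volume`
#'   ([oct_volume()]), `truth` ([label_volume()]), `boundaries` and
#'   `params`.
#' @export
render_phantom <- function(params, noise = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  g <- params$geometry
  set.seed(params$seed)
  bounds <- sample_boundaries(params)
  truth <- labels_from_surfaces(bounds, g)
  d <- dims_of(g)

  img <- array(params$layer_mean_intensity[truth$labels], d)
  # optical depth (mm) below the skin surface, clamped at 0 above it
  z2 <- bounds[[1]]$z
  depth_vox <- rep(seq_len(d[1]), times = d[2] * d[3]) -
    rep(as.vector(z2), each = d[1])
  depth_vox[depth_vox < 0] <- 0
  att <- exp(-params$attenuation_per_mm *
               depth_vox * (g$extent_z_mm / g$n_z))
  dim(att) <- d
  tissue <- truth$labels > 1L
  img[tissue] <- img[tissue] * att[tissue]

  if (noise && is.finite(params$speckle_shape)) {
    k <- params$speckle_shape
    img <- img * stats::rgamma(length(img), shape = k, rate = k)
    dim(img) <- d
  }
  structure(list(volume = oct_volume(img, g,
                                     id = sprintf("phantom_seed%d",
                                                  params$seed)),
                 truth = truth, boundaries = bounds, params = params),
            class = "oct_phantom")
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("oct_phantom (seed %d, speckle shape %s)\n",
              x$params$seed, format(x$params$speckle_shape)))
  print(x$volume)
  invisible(x)
}

#' Generate a cohort of phantom volumes
#'
#' Each volume draws its own layer thicknesses (relative SD
#' `thickness_jitter_frac`, truncated at half the mean) and a sub-seed
#' derived deterministically from `seed`, so the dataset is reproducible
#' and volumes are mutually independent.
#'
#' @param n_volumes Number of phantoms (>= 1); the study cohort used 7.
#' @param params Template [phantom_params()].
#' @param seed Master seed (overrides `params$seed`).
#' @return List of `oct_phantom` objects.
#' @export
make_dataset <- function(n_volumes, params = phantom_params(),
                         seed = params$seed) {
  n_volumes <- as.integer(n_volumes)
  if (is.na(n_volumes) || n_volumes < 1L)
    stop("n_volumes must be >= 1", call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_volumes)
  jitters <- matrix(stats::rnorm(3L * n_volumes, 1,
                                 params$thickness_jitter_frac),
                    nrow = n_volumes)
  jitters <- pmax(jitters, 0.5)
  lapply(seq_len(n_volumes), function(i) {
    p <- params
    p$layer_thickness_um <- params$layer_thickness_um * jitters[i, ]
    p$seed <- sub_seeds[i]
    render_phantom(p)
  })
}
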