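#' Per-class Sørensen–Dice coefficients
#'
#' For each class i, `DSC_i = 2 n_match_i / (n_true_i + n_segm_i)` where
#' `n_match_i` counts voxels labeled i in both volumes. A class absent
#' from both volumes scores 1 by convention. Symmetric in its arguments.
#'
#' @param true,segm [label_volume()]s of identical shape.
#' @return An object of class `dsc_report`: list with `dsc` (length-5
#'   numeric), `n_true`, `n_segm`, `n_match`.
#' @export
dice <- function(true, segm) {
  stopifnot(inherits(true, "label_volume"), inherits(segm, "label_volume"))
  if (!identical(dim(true$labels), dim(segm$labels)))
    stop("label volumes have different shapes", call. = FALSE)
  t <- true$labels; s <- segm$labels
  n_true <- tabulate(t, 5L)
  n_segm <- tabulate(s, 5L)
  n_match <- tabulate(t[t == s], 5L)
  dsc <- ifelse(n_true + n_segm == 0L, 1,
                2 * n_match / (n_true + n_segm))
  structure(list(dsc = dsc, n_true = n_true, n_segm = n_segm,
                 n_match = n_match),
            class = "dsc_report")
}

#' @export
print.dsc_report <- function(x, ...) {
  nm <- oct_class_names()
  cat("Sørensen–Dice coefficients:\n")
  for (i in 1:5)
    cat(sprintf("  %-10s %.4f  (true %d, segm %d, match %d)\n",
                nm[i], x$dsc[i], x$n_true[i], x$n_segm[i], x$n_match[i]))
  cat(sprintf("  mean over tissue classes 2-5: %.4f\n", mean(x$dsc[2:5])))
  invisible(x)
}

#' Geometric layer thickness from a label volume
#'
#' Per lateral column, thickness is the count of voxels of the layer
#' times the optical voxel depth, divided by the tissue refractive index
#' to convert optical path to geometric thickness:
#' `t_um = n_vox * (1000 extent_z_mm / n_z) / n_refr`. The volume mean
#' averages the columns that contain the layer; columns without it are
#' excluded. The dermis (class 5) is rejected because its lower border
#' lies beyond the imaging depth.
#'
#' @param labels A [label_volume()].
#' @param layer Class index in 2..4.
#' @param n_refr Tissue refractive index (default 1.4).
#' @return List with `per_column` (matrix `(n_y, n_x)` of thickness in
#'   um, `NA` where the layer is absent) and `mean_um`.
#' @export
layer_thickness <- function(labels, layer, n_refr = 1.4) {
  stopifnot(inherits(labels, "label_volume"))
  layer <- as.integer(layer)
  if (!(layer %in% 2:4))
    stop("layer must be 2..4 (the dermis lower border is not imaged)",
         call. = FALSE)
  g <- labels$geometry
  counts <- colSums(labels$labels == layer)   # over z -> (n_y, n_x)
  dim(counts) <- c(g$n_y, g$n_x)
  th <- counts * delta_z_opt_um(g) / n_refr
  th[counts == 0L] <- NA_real_
  list(per_column = th, mean_um = mean(th, na.rm = TRUE))
}

#' Cohort thickness statistics
#'
#' Mean and sample SD of the per-volume mean thickness of a layer
#' across a cohort of label volumes (reported as M ± SD).
#'
#' @param label_volumes List of [label_volume()]s.
#' @param layer Class index in 2..4.
#' @param n_refr Tissue refractive index (default 1.4).
#' @return An object of class `thickness_report`: list with `layer`,
#'   `mean_um`, `sd_um` (`NA` for a single volume), `per_volume_um`,
#'   `n_refr`, `delta_z_opt_um`.
#' @export
cohort_thickness <- function(label_volumes, layer, n_refr = 1.4) {
  if (length(label_volumes) < 1L) stop("empty cohort", call. = FALSE)
  per <- vapply(label_volumes,
                function(lv) layer_thickness(lv, layer, n_refr)$mean_um,
                numeric(1))
  structure(list(layer = as.integer(layer),
                 mean_um = mean(per),
                 sd_um = if (length(per) >= 2L) stats::sd(per) else NA_real_,
                 per_volume_um = per, n_refr = n_refr,
                 delta_z_opt_um =
                   delta_z_opt_um(label_volumes[[1]]$geometry)),
            class = "thickness_report")
}

#' @export
print.thickness_report <- function(x, ...) {
  nm <- oct_class_names()
  cat(sprintf("thickness of %s: %.1f +/- %.1f um (n = %d, n_refr = %.2f)\n",
              nm[x$layer], x$mean_um, x$sd_um, length(x$per_volume_um),
              x$n_refr))
  invisible(x)
}
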