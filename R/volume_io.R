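#' Read an OCT intensity or label volume
#'
#' Supports multi-page TIFF stacks (one page per z slice, pages indexed
#' `(y, x)`) and NIfTI-1 volumes. Physical geometry is taken from a JSON
#' sidecar (`<path>.json`, schema
#' `{n_z, n_y, n_x, extent_z_mm, extent_y_mm, extent_x_mm}`) when
#' present, from the NIfTI `pixdim` otherwise, or from `default_geometry`.
#'
#' TIFF cannot hold out-of-range floats, so intensity stacks are stored
#' normalized by a scale factor recorded in the sidecar; reading undoes
#' the scaling. Label volumes round-trip exactly in both formats.
#'
#' @param path File path.
#' @param format `"tiff_stack"` or `"nifti"`; default guessed from the
#'   file extension.
#' @param kind `"intensity"` or `"label"`; default from the sidecar if
#'   present, else `"intensity"`.
#' @param default_geometry Geometry used when no metadata is found.
#' @param id Identifier for the returned volume (default: file name).
#' @return An [oct_volume()] or [label_volume()].
#' @export
read_volume <- function(path, format = NULL,
                        kind = NULL,
                        default_geometry = voxel_geometry(),
                        id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  side <- read_sidecar(path)
  kind <- kind %||% side$kind %||% "intensity"
  kind <- match.arg(kind, c("intensity", "label"))

  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (!is.matrix(pages[[1]]))
      stop("TIFF pages are not single-channel 2D images", call. = FALSE)
    n_z <- length(pages)
    if (n_z < 2L && is.null(side))
      stop("single-page TIFF is a 2D image, not a volume", call. = FALSE)
    d <- c(n_z, nrow(pages[[1]]), ncol(pages[[1]]))
    arr <- array(0, d)
    for (z in seq_len(n_z)) arr[z, , ] <- pages[[z]]
    if (kind == "label") {
      arr <- round(arr * 255)
    } else {
      arr <- arr * (side$scale %||% 1)
    }
  } else if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop("NIfTI content is not 3D (got ", length(dim(arr)), " dims)",
           call. = FALSE)
    arr <- array(as.vector(arr), dim(arr))   # drop image attributes
    if (is.null(side)) {
      pd <- RNifti::pixdim(img)
      if (length(pd) >= 3 && all(pd[1:3] > 0) && any(pd[1:3] != 1))
        side <- list(n_z = dim(arr)[1], n_y = dim(arr)[2], n_x = dim(arr)[3],
                     extent_z_mm = pd[1] * dim(arr)[1],
                     extent_y_mm = pd[2] * dim(arr)[2],
                     extent_x_mm = pd[3] * dim(arr)[3])
    }
  } else stop("unknown format: ", format, call. = FALSE)

  geom <- if (!is.null(side) && !is.null(side$n_z)) {
    voxel_geometry(side$n_z, side$n_y, side$n_x,
                   side$extent_z_mm, side$extent_y_mm, side$extent_x_mm)
  } else {
    g <- default_geometry
    voxel_geometry(dim(arr)[1], dim(arr)[2], dim(arr)[3],
                   g$extent_z_mm * dim(arr)[1] / g$n_z,
                   g$extent_y_mm * dim(arr)[2] / g$n_y,
                   g$extent_x_mm * dim(arr)[3] / g$n_x)
  }
  id <- id %||% basename(path)
  if (kind == "label") label_volume(array(as.integer(arr), dim(arr)), geom)
  else oct_volume(arr, geom, id = id)
}

#' Write an OCT intensity or label volume
#'
#' Inverse of [read_volume()]. Intensities are stored as 32-bit floats
#' (TIFF: normalized by a scale factor kept in the JSON sidecar; NIfTI:
#' raw float), labels as 8-bit integers. A JSON geometry sidecar
#' `<path>.json` is always written.
#'
#' @param vol An [oct_volume()] or [label_volume()].
#' @param path Output file path.
#' @param format `"tiff_stack"` or `"nifti"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  format <- format %||% guess_format(path)
  is_label <- inherits(vol, "label_volume")
  if (!is_label && !inherits(vol, "oct_volume"))
    stop("vol must be an oct_volume or label_volume", call. = FALSE)
  arr <- if (is_label) vol$labels else vol$intensity
  g <- vol$geometry
  side <- list(n_z = g$n_z, n_y = g$n_y, n_x = g$n_x,
               extent_z_mm = g$extent_z_mm, extent_y_mm = g$extent_y_mm,
               extent_x_mm = g$extent_x_mm,
               kind = if (is_label) "label" else "intensity")

  if (format == "tiff_stack") {
    if (is_label) {
      pages <- lapply(seq_len(g$n_z), function(z) arr[z, , ] / 255)
      ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                silent = TRUE)
    } else {
      scale <- max(arr, 1e-12)
      side$scale <- scale
      pages <- lapply(seq_len(g$n_z), function(z) arr[z, , ] / scale)
      ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                silent = TRUE)
    }
    if (inherits(ok, "try-error"))
      stop("cannot write TIFF at ", path, call. = FALSE)
  } else if (format == "nifti") {
    pd <- c(g$extent_z_mm / g$n_z, g$extent_y_mm / g$n_y,
            g$extent_x_mm / g$n_x)
    img <- RNifti::asNifti(if (is_label) arr else arr * 1.0)
    RNifti::pixdim(img) <- pd
    ok <- try(RNifti::writeNifti(img, path,
                                 datatype = if (is_label) "uint8"
                                 else "float"),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("cannot write NIfTI at ", path, call. = FALSE)
  } else stop("unknown format: ", format, call. = FALSE)

  ok <- try(write_sidecar(path, side), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write sidecar for ", path, call. = FALSE)
  invisible(path)
}

#' Central crop along the slow lateral axis
#'
#' Keeps a centred window of `target_x` voxels along `x`, trimming the
#' distorted B-scan borders; for an odd remainder the extra voxel is
#' trimmed from the high-index side. The per-voxel physical size is
#' preserved (the lateral extent is rescaled proportionally); `z` and `y`
#' are untouched. A full-field 256 x 512 x 512 acquisition cropped to
#' `target_x = 256` gives the standard 256 x 512 x 256 study volume.
#'
#' @param vol An [oct_volume()] or [label_volume()].
#' @param target_x Number of x voxels to keep (<= `n_x`).
#' @return A cropped volume of the same class.
#' @export
central_crop <- function(vol, target_x) {
  is_label <- inherits(vol, "label_volume")
  if (!is_label && !inherits(vol, "oct_volume"))
    stop("vol must be an oct_volume or label_volume", call. = FALSE)
  g <- vol$geometry
  target_x <- as.integer(target_x)
  if (target_x < 1L || target_x > g$n_x)
    stop("target_x must be in 1..n_x", call. = FALSE)
  lo <- (g$n_x - target_x) %/% 2L          # voxels removed on the low side
  idx <- (lo + 1L):(lo + target_x)
  geom <- voxel_geometry(g$n_z, g$n_y, target_x,
                         g$extent_z_mm, g$extent_y_mm,
                         g$extent_x_mm * target_x / g$n_x)
  if (is_label) {
    label_volume(vol$labels[, , idx, drop = FALSE], geom)
  } else {
    oct_volume(vol$intensity[, , idx, drop = FALSE], geom, id = vol$id)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         tif = , tiff = "tiff_stack",
         nii = "nifti",
         stop("cannot guess format from extension '", ext, "'",
              call. = FALSE))
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

write_sidecar <- function(path, side) {
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}
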