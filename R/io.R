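# TIFF input/output, Z-projection and physical field geometry.
# Reading and writing go through the `tiff` package; intensities are kept on
# their native integer scale (AU in [0, 65535] for 16-bit files).

#' Read a grayscale TIFF as a calibrated image stack
#'
#' Loads a single- or multi-page grayscale TIFF into an [image_stack()].
#' Multi-channel (e.g. RGB) pages are refused unless an explicit `channel`
#' index selects one plane — no silent channel guessing.
#'
#' @param path Path to the TIFF file.
#' @param microns_per_pixel Lateral calibration, um/px (> 0); the file's own
#'   resolution tags are not trusted.
#' @param z_step_um Axial slice spacing, um (> 0). Irrelevant but still
#'   required for single-page files so downstream volume arithmetic is never
#'   silently uncalibrated.
#' @param channel Optional integer channel index for multi-channel input.
#' @param tile_grid Integer pair recorded as acquisition metadata.
#'
#' @return An [image_stack()] with z-dimension equal to the page count
#'   (1 for a single-page file).
#' @export
read_stack <- function(path, microns_per_pixel, z_step_um, channel = NULL,
                       tile_grid = c(1L, 1L)) {
  if (!file.exists(path)) abort(sprintf("Cannot read '%s': no such file.", path))
  if (missing(microns_per_pixel) || missing(z_step_um)) {
    abort("Calibration (`microns_per_pixel`, `z_step_um`) must be supplied.")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) abort(sprintf(
                      "Failed to parse '%s' as TIFF: %s", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (is.null(channel)) {
        abort(paste0("'", path, "' is multi-channel; pass `channel` to select ",
                     "one plane explicitly."))
      }
      if (channel > dim(p)[3]) abort("`channel` exceeds the number of channels.")
      p <- p[, , channel]
    }
    p
  })
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), TRUE))) {
    abort("All TIFF pages must share the same dimensions.")
  }
  voxels <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) voxels[k, , ] <- pages[[k]]
  image_stack(voxels, microns_per_pixel, z_step_um, tile_grid = tile_grid,
              provenance = path)
}

#' Write frames or stacks as 16-bit grayscale TIFF
#'
#' Intensities are rounded, clamped to \[0, 65535\] and stored as 16-bit
#' samples, the common dialect of fluorescence microscopy exports; a write
#' followed by [read_stack()] reproduces the rounded pixels exactly.
#'
#' @param x An [image_frame()], an [image_stack()], or a list of frames
#'   (written as a multi-page file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path) {
  to_unit <- function(m) {
    m <- round(pmin(pmax(m, 0), INTENSITY_MAX))
    m / INTENSITY_MAX
  }
  pages <- if (inherits(x, "image_frame")) {
    list(to_unit(as_plain_matrix(x)))
  } else if (inherits(x, "image_stack")) {
    lapply(seq_len(dim(x)[1]), function(k) to_unit(unclass(x)[k, , ]))
  } else if (is.list(x)) {
    lapply(x, function(f) to_unit(as_plain_matrix(f)))
  } else {
    abort("`x` must be an image_frame, image_stack, or list of frames.")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Z-project a stack to a single frame
#'
#' Collapses the z-dimension by the per-pixel maximum (the standard choice
#' for sparse fluorescent networks) or mean. Calibration is propagated and
#' the projection method recorded in the frame's provenance. Projecting a
#' single-slice stack is the identity.
#'
#' @param stack An [image_stack()].
#' @param method `"max"` (default) or `"mean"`.
#' @param day Optional day label stamped on the frame.
#' @return An [image_frame()].
#' @export
z_project <- function(stack, method = c("max", "mean"), day = NA_integer_) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  v <- unclass(stack)
  attributes(v) <- list(dim = dim(stack))
  proj <- if (method == "max") {
    apply(v, c(2, 3), max)
  } else {
    apply(v, c(2, 3), mean)
  }
  image_frame(
    proj,
    microns_per_pixel = attr(stack, "microns_per_pixel"),
    provenance = sprintf("%s-projection of %s", method, attr(stack, "provenance")),
    day = day
  )
}

#' Imaged area and volume of an acquisition
#'
#' Computes the physical footprint of a stack (or of a directly supplied
#' area, when the instrument reports one) and the imaged volume
#' `area x z-extent`. The z-extent is slice count times slice spacing.
#'
#' @param stack An [image_stack()]; omit to supply `area_mm2`/`depth_um`
#'   directly.
#' @param area_mm2,depth_um Direct overrides for the imaged area and depth.
#' @param digits Decimal places for the reported volume (default 1).
#' @return A tibble with `area_mm2`, `depth_um`, `volume_mm3`.
#' @export
#' @examples
#' imaged_geometry(area_mm2 = 13.8, depth_um = 225)
imaged_geometry <- function(stack = NULL, area_mm2 = NULL, depth_um = NULL,
                            digits = 1) {
  if (!is.null(stack)) {
    stopifnot(inherits(stack, "image_stack"))
    mpp <- attr(stack, "microns_per_pixel")
    d <- dim(stack)
    if (is.null(area_mm2)) area_mm2 <- d[2] * d[3] * mpp^2 / 1e6
    if (is.null(depth_um)) depth_um <- d[1] * attr(stack, "z_step_um")
  }
  if (is.null(area_mm2) || is.null(depth_um)) {
    abort("Supply a stack or both `area_mm2` and `depth_um`.")
  }
  if (depth_um <= 0) abort("The z-extent must be > 0.")
  tibble(
    area_mm2 = area_mm2,
    depth_um = depth_um,
    volume_mm3 = round(area_mm2 * depth_um / 1000, digits)
  )
}
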