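#' Calibrated 2-D grayscale image frame
#'
#' The basic raster container every measurement operates on: a numeric matrix
#' of pixel intensities (rows = y, columns = x, arbitrary units) together with
#' the physical pixel size. A short free-text provenance string records where
#' the frame came from (file path, projection method, day label).
#'
#' @param pixels Numeric matrix of non-negative intensities (y by x).
#' @param microns_per_pixel Physical pixel size in micrometres, > 0.
#' @param provenance Free-text provenance, e.g. `"max-projection of stack.tif"`.
#' @param day Optional integer day label carried through timecourses.
#'
#' @return An `image_frame` object (a matrix with calibration attributes).
#' @export
#' @examples
#' f <- image_frame(matrix(0, 32, 32), microns_per_pixel = 4)
#' frame_field_um(f)
image_frame <- function(pixels, microns_per_pixel, provenance = "in-memory",
                        day = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    abort("`pixels` must be non-negative and free of NA.")
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      microns_per_pixel <= 0) {
    abort("`microns_per_pixel` must be a single positive number.")
  }
  structure(
    pixels,
    microns_per_pixel = as.numeric(microns_per_pixel),
    provenance = as.character(provenance),
    day = as.integer(day),
    class = c("image_frame", "matrix", "array")
  )
}

#' @export
print.image_frame <- function(x, ...) {
  mpp <- attr(x, "microns_per_pixel")
  cat(sprintf(
    "<image_frame> %d x %d px @ %.3g um/px (%.3g x %.3g mm)\n",
    nrow(x), ncol(x), mpp, nrow(x) * mpp / 1000, ncol(x) * mpp / 1000
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]; provenance: %s\n",
              min(x), max(x), attr(x, "provenance")))
  invisible(x)
}

#' @rdname image_frame
#' @param frame An `image_frame`.
#' @return `frame_field_um()`: the physical field size in micrometres
#'   (height, width).
#' @export
frame_field_um <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  dim(frame) * attr(frame, "microns_per_pixel")
}

#' @rdname image_frame
#' @export
frame_calibration <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  attr(frame, "microns_per_pixel")
}

as_plain_matrix <- function(frame) {
  m <- unclass(frame)
  attributes(m) <- list(dim = dim(frame))
  m
}

#' Calibrated 3-D image stack
#'
#' A z-by-y-by-x voxel array with lateral and axial calibration, as produced
#' by confocal tile scans. Tile geometry is carried as metadata only; inputs
#' are assumed already stitched.
#'
#' @param voxels Numeric 3-D array (z, y, x), non-negative intensities.
#' @param microns_per_pixel Lateral pixel size in micrometres, > 0.
#' @param z_step_um Axial slice spacing in micrometres, > 0.
#' @param tile_grid Integer pair (rows, cols) of the acquisition tiling;
#'   metadata only.
#' @param provenance Free-text provenance.
#'
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, microns_per_pixel, z_step_um,
                        tile_grid = c(1L, 1L), provenance = "in-memory") {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3-D array (z, y, x).")
  }
  if (anyNA(voxels) || any(voxels < 0)) {
    abort("`voxels` must be non-negative and free of NA.")
  }
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0 ||
      !is.numeric(z_step_um) || z_step_um <= 0) {
    abort("Calibration values `microns_per_pixel` and `z_step_um` must be > 0.")
  }
  structure(
    voxels,
    microns_per_pixel = as.numeric(microns_per_pixel),
    z_step_um = as.numeric(z_step_um),
    tile_grid = as.integer(tile_grid),
    provenance = as.character(provenance),
    class = c("image_stack", "array")
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> %d slices of %d x %d px @ %.3g um/px, z-step %.3g um\n",
    d[1], d[2], d[3], attr(x, "microns_per_pixel"), attr(x, "z_step_um")
  ))
  invisible(x)
}
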