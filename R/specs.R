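#' Synthetic ring-network image specification
#'
#' Parameters of the noiseless ideal image: a bright annular condensate with a
#' radially Gaussian cross-section (its FWHM is the ring "thickness") over a
#' dimmer background of branched filaments, mimicking a sound-patterned
#' microcapillary ring plus its surrounding capillary sprouts. Defaults follow
#' the measured geometry of the emulated system: a 3.58 mm square field imaged
#' at 4 um/px, ring diameter 1781 um and thickness 416 um.
#'
#' @param image_size_px Integer pair (rows, cols) of the rendered frame.
#' @param microns_per_pixel Pixel size in micrometres, > 0.
#' @param ring_diameter_um Diameter of the annulus (peak-to-peak), um.
#' @param ring_thickness_um FWHM of the annular Gaussian cross-section, um.
#' @param ring_amplitude Peak intensity of the annulus, arbitrary units in
#'   \[0, 65535\].
#' @param arc_fraction Fraction of the 360 degree arc rendered, in (0, 1\];
#'   1 is a fully continuous ring.
#' @param gap_layout Either `"random"` (a single contiguous gap with a seeded
#'   uniform start angle) or a list of `c(start, end)` angle pairs in radians.
#' @param center_offset_um Numeric pair (x, y): ring centre minus image
#'   centre, um.
#' @param background_amplitude Peak intensity of a single background filament.
#' @param n_branches Number of background filaments (non-negative integer).
#' @param branch_length_um Nominal filament length, um.
#' @param branch_width_um FWHM of the filament transverse profile, um.
#' @param seed Integer seed controlling gap placement and filament walks.
#'
#' @return A validated `ring_spec` list.
#' @export
#' @examples
#' spec <- ring_spec(image_size_px = c(256, 256), microns_per_pixel = 14)
ring_spec <- function(image_size_px = c(895L, 895L),
                      microns_per_pixel = 4,
                      ring_diameter_um = 1781,
                      ring_thickness_um = 416,
                      ring_amplitude = 20000,
                      arc_fraction = 1,
                      gap_layout = "random",
                      center_offset_um = c(0, 0),
                      background_amplitude = 5000,
                      n_branches = 40L,
                      branch_length_um = 600,
                      branch_width_um = 20,
                      seed = 1L) {
  spec <- list(
    image_size_px = as.integer(image_size_px),
    microns_per_pixel = microns_per_pixel,
    ring_diameter_um = ring_diameter_um,
    ring_thickness_um = ring_thickness_um,
    ring_amplitude = ring_amplitude,
    arc_fraction = arc_fraction,
    gap_layout = gap_layout,
    center_offset_um = center_offset_um,
    background_amplitude = background_amplitude,
    n_branches = as.integer(n_branches),
    branch_length_um = branch_length_um,
    branch_width_um = branch_width_um,
    seed = as.integer(seed)
  )
  validate_ring_spec(spec)
  structure(spec, class = "ring_spec")
}

validate_ring_spec <- function(spec) {
  with(spec, {
    if (length(image_size_px) != 2 || any(image_size_px < 8)) {
      abort("`image_size_px` must be two integers >= 8.")
    }
    if (microns_per_pixel <= 0) abort("`microns_per_pixel` must be > 0.")
    if (ring_diameter_um <= 0 || ring_thickness_um <= 0) {
      abort("Ring diameter and thickness must be > 0.")
    }
    if (ring_amplitude < 0 || background_amplitude < 0) {
      abort("Amplitudes must be >= 0.")
    }
    if (arc_fraction <= 0 || arc_fraction > 1) {
      abort("`arc_fraction` must lie in (0, 1].")
    }
    if (n_branches < 0) abort("`n_branches` must be >= 0.")
    if (branch_width_um <= 0 || branch_length_um <= 0) {
      abort("Branch length and width must be > 0.")
    }
    field_um <- min(image_size_px) * microns_per_pixel
    outer_radius <- ring_diameter_um / 2 + ring_thickness_um
    if (outer_radius + max(abs(center_offset_um)) > field_um / 2) {
      abort(paste0(
        "Ring geometry exceeds the field: outer radius ",
        round(outer_radius), " um (+ offset) does not fit in a ",
        round(field_um), " um field."
      ), class = "ringprofiler_geometry_error")
    }
  })
  invisible(spec)
}

#' Synthetic acquisition-noise specification
#'
#' Noise applied to the ideal image, in rendering order: multiplicative linear
#' shading across the field, Poisson shot noise, additive Gaussian read noise,
#' and clamping to the 16-bit range. The emulated micrographs carry no
#' published noise characterisation, so the defaults are chosen for plausible
#' fluorescence statistics rather than fitted to data: shot noise at roughly
#' 100 detected photons per 10000 intensity units and read noise around 1.5 %
#' of the default ring amplitude.
#'
#' @param gaussian_sigma SD of additive read noise, intensity AU (0 disables).
#' @param poisson_scale Photon-count conversion, counts per intensity AU
#'   (0 disables shot noise).
#' @param background_gradient Maximum fractional shading across the field
#'   (0 disables); intensity ramps linearly from 1 to `1 - background_gradient`
#'   left to right.
#' @param seed Integer seed for the noise draws.
#'
#' @return A validated `noise_spec` list.
#' @export
#' @examples
#' noise_spec()           # default noise
#' noise_spec(0, 0, 0)    # noiseless
noise_spec <- function(gaussian_sigma = 300,
                       poisson_scale = 0.01,
                       background_gradient = 0.1,
                       seed = 1L) {
  if (gaussian_sigma < 0 || poisson_scale < 0 || background_gradient < 0 ||
      background_gradient >= 1) {
    abort("Noise parameters must be >= 0 (gradient < 1).")
  }
  structure(
    list(
      gaussian_sigma = gaussian_sigma,
      poisson_scale = poisson_scale,
      background_gradient = background_gradient,
      seed = as.integer(seed)
    ),
    class = "noise_spec"
  )
}

#' Day-indexed dynamics specification for synthetic timecourses
#'
#' Programs how the synthetic network evolves over culture days relative to
#' the day -1 baseline: the target total foreground-area ratio, the ring
#' thickness ratio, and the ring continuity (arc fraction) per day. The
#' trajectories are user inputs, not claims; they let a programmed growth or
#' regression be recovered by the measurement pipeline.
#'
#' @param days Ordered integer day labels; must contain the baseline day -1.
#' @param area_multiplier Numeric vector (one per day) of target total
#'   foreground area relative to day -1; the day -1 entry must be 1.
#' @param thickness_multiplier Ring thickness relative to day -1 (day -1
#'   entry 1).
#' @param continuity Arc fraction per day, each in (0, 1].
#'
#' @return A validated `dynamics_spec` list.
#' @export
#' @examples
#' dynamics_spec(
#'   days = -1:4,
#'   area_multiplier = c(1, 1.2, 1.45, 1.3, 1.15, 1.0)
#' )
dynamics_spec <- function(days,
                          area_multiplier = rep(1, length(days)),
                          thickness_multiplier = rep(1, length(days)),
                          continuity = rep(1, length(days))) {
  days <- as.integer(days)
  if (is.unsorted(days, strictly = TRUE)) abort("`days` must be strictly increasing.")
  if (!(-1L %in% days)) abort("The baseline day -1 must be present in `days`.")
  n <- length(days)
  if (length(area_multiplier) != n || length(thickness_multiplier) != n ||
      length(continuity) != n) {
    abort("All per-day vectors must have one entry per day.")
  }
  if (any(area_multiplier <= 0) || any(thickness_multiplier <= 0)) {
    abort("Multipliers must be > 0.")
  }
  i0 <- match(-1L, days)
  if (area_multiplier[i0] != 1 || thickness_multiplier[i0] != 1) {
    abort("Day -1 multipliers must equal 1 (it is the baseline).")
  }
  if (any(continuity <= 0 | continuity > 1)) {
    abort("`continuity` values must lie in (0, 1].")
  }
  structure(
    list(
      days = days,
      area_multiplier = setNames(area_multiplier, days),
      thickness_multiplier = setNames(thickness_multiplier, days),
      continuity = setNames(continuity, days)
    ),
    class = "dynamics_spec"
  )
}
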