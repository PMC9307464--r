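# Synthetic fluorescence-like ring-network image generation with exact
# ground truth. All randomness is drawn under local seeds so identical
# (spec, noise) inputs reproduce images bit-for-bit.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2)) # 2.3548...
INTENSITY_MAX <- 65535

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# pixel-centre coordinate grids in um; rows = y, cols = x
pixel_grid_um <- function(size_px, mpp) {
  list(
    x = (seq_len(size_px[2]) - 0.5) * mpp,
    y = (seq_len(size_px[1]) - 0.5) * mpp
  )
}

# resolve arc gaps to a list of (start, end) pairs in [0, 2*pi), under the
# spec seed when layout is "random" (single contiguous gap)
resolve_gaps <- function(spec) {
  if (spec$arc_fraction >= 1) return(list())
  if (identical(spec$gap_layout, "random")) {
    width <- 2 * pi * (1 - spec$arc_fraction)
    start <- with_seed(spec$seed, runif(1, 0, 2 * pi))
    return(list(c(start, start + width) %% (2 * pi)))
  }
  gaps <- lapply(spec$gap_layout, function(g) as.numeric(g) %% (2 * pi))
  total <- sum(vapply(gaps, function(g) (g[2] - g[1]) %% (2 * pi), 0))
  if (abs(total - 2 * pi * (1 - spec$arc_fraction)) > 0.02 * 2 * pi) {
    abort("Explicit `gap_layout` is inconsistent with `arc_fraction`.")
  }
  gaps
}

angle_in_gap <- function(theta, gap) {
  if (gap[1] <= gap[2]) theta >= gap[1] & theta < gap[2]
  else theta >= gap[1] | theta < gap[2]
}

# noiseless annulus: Gaussian in radius, FWHM = ring_thickness_um, times an
# angular indicator leaving the configured gaps dark
render_ring_component <- function(spec, thickness_um = spec$ring_thickness_um,
                                  arc_fraction = spec$arc_fraction) {
  size <- spec$image_size_px
  mpp <- spec$microns_per_pixel
  g <- pixel_grid_um(size, mpp)
  cx <- size[2] * mpp / 2 + spec$center_offset_um[1]
  cy <- size[1] * mpp / 2 + spec$center_offset_um[2]
  dx <- matrix(g$x - cx, nrow = size[1], ncol = size[2], byrow = TRUE)
  dy <- matrix(g$y - cy, nrow = size[1], ncol = size[2])
  r <- sqrt(dx^2 + dy^2)
  sigma <- thickness_um / FWHM_PER_SIGMA
  img <- spec$ring_amplitude * exp(-(r - spec$ring_diameter_um / 2)^2 / (2 * sigma^2))
  spec2 <- spec
  spec2$arc_fraction <- arc_fraction
  gaps <- resolve_gaps(spec2)
  if (length(gaps) > 0) {
    theta <- atan2(dy, dx) %% (2 * pi)
    keep <- matrix(TRUE, size[1], size[2])
    for (gp in gaps) keep <- keep & !angle_in_gap(theta, gp)
    img <- img * keep
  }
  img
}

# seeded smooth random-walk filament paths in pixel units; walks reflect at
# the field borders so extending a walk never leaves the image
generate_walks <- function(n, n_steps, size_px, seed, curvature = 0.12) {
  if (n == 0) return(list())
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pos <- matrix(NA_real_, nrow = n_steps + 1, ncol = 2)
      pos[1, ] <- c(runif(1, 1, size_px[2]), runif(1, 1, size_px[1]))
      dir <- runif(1, 0, 2 * pi)
      turns <- rnorm(n_steps, 0, curvature)
      for (k in seq_len(n_steps)) {
        dir <- dir + turns[k]
        p <- pos[k, ] + c(cos(dir), sin(dir))
        if (p[1] < 1 || p[1] > size_px[2]) {
          dir <- pi - dir
          p <- pos[k, ] + c(cos(dir), sin(dir))
        }
        if (p[2] < 1 || p[2] > size_px[1]) {
          dir <- -dir
          p <- pos[k, ] + c(cos(dir), sin(dir))
        }
        pos[k + 1, ] <- pmin(pmax(p, 1), c(size_px[2], size_px[1]))
      }
      pos
    })
  })
}

# rasterize walk prefixes (first `n_steps` steps of each walk) and blur to a
# Gaussian transverse profile whose peak is background_amplitude per filament
render_branches <- function(spec, walks, n_steps = NULL) {
  size <- spec$image_size_px
  if (length(walks) == 0 || spec$background_amplitude == 0) {
    return(matrix(0, size[1], size[2]))
  }
  stamps <- matrix(0, size[1], size[2])
  for (w in walks) {
    k <- if (is.null(n_steps)) nrow(w) else min(n_steps + 1, nrow(w))
    if (k < 2) next
    ij <- cbind(round(w[seq_len(k), 2]), round(w[seq_len(k), 1])) # row=y, col=x
    ij[, 1] <- pmin(pmax(ij[, 1], 1), size[1])
    ij[, 2] <- pmin(pmax(ij[, 2], 1), size[2])
    idx <- (ij[, 2] - 1) * size[1] + ij[, 1]
    counts <- tabulate(idx, nbins = size[1] * size[2])
    stamps <- stamps + counts
  }
  sigma_px <- spec$branch_width_um / FWHM_PER_SIGMA / spec$microns_per_pixel
  blurred <- EBImage::gblur(stamps, sigma = sigma_px)
  blurred[blurred < 0] <- 0
  blurred * spec$background_amplitude * sqrt(2 * pi) * sigma_px
}

# Foreground bookkeeping: the ideal (noiseless) image thresholded at half
# the amplitude of the dimmest structure present — one global half-maximum
# rule, so a measurement that thresholds the whole image with a single value
# can reproduce the truth footprint. (Per-component half-max masks would be
# irreproducible by any global threshold when the ring and the filaments
# have different amplitudes.)
truth_threshold <- function(spec, with_ring = TRUE) {
  amps <- c(
    if (with_ring && spec$ring_amplitude > 0) spec$ring_amplitude,
    if (spec$n_branches > 0 && spec$background_amplitude > 0) spec$background_amplitude
  )
  if (length(amps) == 0) Inf else min(amps) / 2
}

truth_mask <- function(ideal, spec, with_ring = TRUE) {
  ideal > truth_threshold(spec, with_ring = with_ring)
}

apply_noise <- function(ideal, noise) {
  img <- ideal
  if (noise$background_gradient > 0) {
    shade <- 1 - noise$background_gradient *
      (seq_len(ncol(img)) - 1) / max(ncol(img) - 1, 1)
    img <- sweep(img, 2, shade, `*`)
  }
  with_seed(noise$seed, {
    if (noise$poisson_scale > 0) {
      img[] <- rpois(length(img), img * noise$poisson_scale) / noise$poisson_scale
    }
    if (noise$gaussian_sigma > 0) {
      img <- img + rnorm(length(img), 0, noise$gaussian_sigma)
    }
  })
  pmin(pmax(img, 0), INTENSITY_MAX)
}

truth_row <- function(spec, area_px, day = NA_integer_, has_ring = TRUE,
                      thickness_um = spec$ring_thickness_um,
                      arc_fraction = spec$arc_fraction) {
  size <- spec$image_size_px
  mpp <- spec$microns_per_pixel
  tibble(
    day = as.integer(day),
    center_x_px = size[2] / 2 + spec$center_offset_um[1] / mpp,
    center_y_px = size[1] / 2 + spec$center_offset_um[2] / mpp,
    radius_um = if (has_ring) spec$ring_diameter_um / 2 else NA_real_,
    thickness_um = if (has_ring) thickness_um else NA_real_,
    arc_fraction = if (has_ring) arc_fraction else NA_real_,
    area_um2 = area_px * mpp^2,
    seed = spec$seed
  )
}

#' Generate a synthetic ring-network image with known ground truth
#'
#' Renders the noiseless ideal — an annulus with radially Gaussian
#' cross-section (peak at radius `ring_diameter_um / 2`, FWHM
#' `ring_thickness_um`), masked to `arc_fraction` of the circle, plus
#' `n_branches` smooth random filaments — then applies the configured noise.
#' The returned ground truth records the true centre, radius, thickness, arc
#' fraction and foreground area (pixels at or above half the component
#' amplitude) of the ideal image.
#'
#' @param spec A [ring_spec()].
#' @param noise A [noise_spec()]; use `noise_spec(0, 0, 0)` for a noiseless
#'   render.
#' @param day Optional integer day label stamped on the frame and truth row.
#'
#' @return A list with elements `frame` (an [image_frame()]) and `truth`
#'   (a one-row tibble).
#' @export
#' @examples
#' sim <- generate_ring_image(
#'   ring_spec(image_size_px = c(128, 128), microns_per_pixel = 28),
#'   noise_spec(0, 0, 0)
#' )
#' sim$truth
generate_ring_image <- function(spec, noise = noise_spec(), day = NA_integer_) {
  validate_ring_spec(spec)
  ring <- render_ring_component(spec)
  walks <- generate_walks(spec$n_branches,
                          round(spec$branch_length_um / spec$microns_per_pixel),
                          spec$image_size_px, seed = spec$seed + 1L)
  branches <- render_branches(spec, walks)
  mask <- truth_mask(ring + branches, spec)
  frame <- image_frame(
    apply_noise(ring + branches, noise),
    microns_per_pixel = spec$microns_per_pixel,
    provenance = sprintf("synthetic ring (seed %d)", spec$seed),
    day = day
  )
  list(frame = frame, truth = truth_row(spec, sum(mask), day = day))
}

#' Generate a synthetic randomly organised network image
#'
#' The unpatterned control: filaments distributed uniformly over the field
#' with no annular component. Ground truth records the foreground area; ring
#' geometry fields are `NA`.
#'
#' @inheritParams generate_ring_image
#' @return A list with elements `frame` and `truth` as in
#'   [generate_ring_image()].
#' @export
generate_network_image <- function(spec, noise = noise_spec(), day = NA_integer_) {
  validate_ring_spec(spec)
  walks <- generate_walks(spec$n_branches,
                          round(spec$branch_length_um / spec$microns_per_pixel),
                          spec$image_size_px, seed = spec$seed + 1L)
  branches <- render_branches(spec, walks)
  mask <- truth_mask(branches, spec, with_ring = FALSE)
  frame <- image_frame(
    apply_noise(branches, noise),
    microns_per_pixel = spec$microns_per_pixel,
    provenance = sprintf("synthetic random network (seed %d)", spec$seed),
    day = day
  )
  list(frame = frame, truth = truth_row(spec, sum(mask), day = day,
                                        has_ring = FALSE))
}

# foreground area (px) of a day's ideal render
day_union_area <- function(ring, branches, spec) {
  sum(truth_mask(ring + branches, spec))
}

#' Generate a day-indexed synthetic timecourse
#'
#' One frame per day of `dynamics`. The ring thickness and arc fraction
#' follow their per-day maps directly; the total foreground area is driven to
#' `area_multiplier` times the day -1 area by deterministically extending or
#' truncating the filament walks (bisection on the shared walk length until
#' the rendered ideal area is within `area_tol` of target). Per-day noise
#' seeds are derived from `noise$seed` so days differ but the whole series is
#' reproducible.
#'
#' @inheritParams generate_ring_image
#' @param dynamics A [dynamics_spec()].
#' @param area_tol Relative tolerance for matching the programmed area
#'   multiplier (default 0.01).
#' @return A list with `frames` (list of [image_frame()], named by day) and
#'   `truth` (tibble, one row per day).
#' @export
generate_timecourse <- function(spec, noise = noise_spec(), dynamics,
                                area_tol = 0.01) {
  validate_ring_spec(spec)
  stopifnot(inherits(dynamics, "dynamics_spec"))
  base_steps <- round(spec$branch_length_um / spec$microns_per_pixel)
  max_scale <- 14
  walks <- generate_walks(spec$n_branches, ceiling(base_steps * max_scale),
                          spec$image_size_px, seed = spec$seed + 1L)

  # baseline day -1
  ring0 <- render_ring_component(spec)
  br0 <- render_branches(spec, walks, n_steps = base_steps)
  base_area <- day_union_area(ring0, br0, spec)
  if (base_area == 0) abort("Baseline image has no foreground; raise amplitudes.")

  frames <- list()
  truth <- list()
  for (i in seq_along(dynamics$days)) {
    d <- dynamics$days[i]
    th <- spec$ring_thickness_um * dynamics$thickness_multiplier[i]
    af <- dynamics$continuity[i]
    spec_d <- spec
    spec_d$ring_thickness_um <- th
    spec_d$arc_fraction <- af
    validate_ring_spec(spec_d)
    ring_d <- render_ring_component(spec, thickness_um = th, arc_fraction = af)
    target <- dynamics$area_multiplier[i] * base_area

    if (d == -1L ||
        (dynamics$area_multiplier[i] == 1 &&
         th == spec$ring_thickness_um && af == spec$arc_fraction)) {
      br_d <- br0
    } else {
      area_at <- function(s) {
        day_union_area(ring_d, render_branches(spec, walks,
                                               n_steps = round(base_steps * s)),
                       spec)
      }
      lo <- 0; hi <- max_scale
      if (area_at(hi) < target * (1 - area_tol)) {
        abort(sprintf(
          "Day %d area multiplier %.2f is unreachable within the field.",
          d, dynamics$area_multiplier[i]))
      }
      if (area_at(lo) > target * (1 + area_tol)) {
        abort(sprintf(
          "Day %d area multiplier %.2f is below the ring's own area.",
          d, dynamics$area_multiplier[i]))
      }
      for (it in seq_len(24)) {
        mid <- (lo + hi) / 2
        a <- area_at(mid)
        if (abs(a - target) <= area_tol * target) { lo <- hi <- mid; break }
        if (a < target) lo <- mid else hi <- mid
      }
      br_d <- render_branches(spec, walks,
                              n_steps = round(base_steps * (lo + hi) / 2))
    }

    area_px <- day_union_area(ring_d, br_d, spec)
    noise_d <- noise
    noise_d$seed <- noise$seed + i
    frames[[as.character(d)]] <- image_frame(
      apply_noise(ring_d + br_d, noise_d),
      microns_per_pixel = spec$microns_per_pixel,
      provenance = sprintf("synthetic timecourse day %d (seed %d)", d, spec$seed),
      day = d
    )
    truth[[i]] <- truth_row(spec, area_px, day = d,
                            thickness_um = th, arc_fraction = af)
  }
  list(frames = frames, truth = dplyr::bind_rows(truth))
}

#' Generate a replicate set with sampled ring geometry
#'
#' Draws diameter and thickness independently per replicate from normal laws
#' (truncated by rejection to geometries that fit the field) and renders one
#' ring image per replicate, emulating pattern-to-pattern variability across
#' wells.
#'
#' @param n Number of replicates (>= 2).
#' @param spec A [ring_spec()] whose diameter and thickness act as the means.
#' @param diameter_sd,thickness_sd SDs of the normal laws, um (>= 0).
#' @inheritParams generate_ring_image
#' @return A list with `sims` (list of per-replicate `list(frame, truth)`)
#'   and `truth` (tibble, one row per replicate with a `replicate` column).
#' @export
generate_replicates <- function(n, spec, diameter_sd = 142, thickness_sd = 124,
                                noise = noise_spec()) {
  if (n < 2) abort("`n` must be >= 2.")
  if (diameter_sd < 0 || thickness_sd < 0) abort("SDs must be >= 0.")
  validate_ring_spec(spec)
  draws <- with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(1000)) {
        di <- rnorm(1, spec$ring_diameter_um, diameter_sd)
        th <- rnorm(1, spec$ring_thickness_um, thickness_sd)
        ok <- di > 0 && th > 0 && !inherits(tryCatch({
          s <- spec; s$ring_diameter_um <- di; s$ring_thickness_um <- th
          validate_ring_spec(s)
        }, error = function(e) e), "error")
        if (ok) return(c(di, th))
      }
      abort("Could not draw a valid ring geometry in 1000 attempts; the truncation is degenerate.")
    })
  })
  sims <- lapply(seq_len(n), function(i) {
    s <- spec
    s$ring_diameter_um <- draws[[i]][1]
    s$ring_thickness_um <- draws[[i]][2]
    s$seed <- spec$seed + i
    nz <- noise
    nz$seed <- noise$seed + i
    generate_ring_image(s, nz)
  })
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  truth$replicate <- seq_len(n)
  list(sims = sims, truth = truth)
}
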