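# The radial intensity profile: aggregated intensity versus radial distance
# from a centre, swept over 360 degrees. This is the statistic from which the
# ring readouts (radius, thickness, AUC, continuity proxy) derive.

#' Estimate the ring-pattern centre of a frame
#'
#' Three placement rules:
#' * `intensity_centroid` — the intensity-weighted centroid of the frame; the
#'   automatic default, exact for symmetric patterns.
#' * `refined` — starts at the centroid, locates the annulus crest (pixels
#'   above the profile's half-maximum level in the peak band, with sparsely
#'   occupied angular sectors dropped as gaps) and fits a circle to those
#'   crest pixels by intensity-weighted least squares, iterating a few
#'   times. Needed for broken rings, where the centroid is biased toward
#'   the remaining arc; recovers the true centre to about a pixel even for
#'   half rings.
#' * `provided` — passes `center` through unchanged (the manual-ROI
#'   workflow).
#'
#' @param frame An [image_frame()].
#' @param method One of `"intensity_centroid"`, `"refined"`, `"provided"`.
#' @param center Numeric pair `c(x_px, y_px)`, required for
#'   `method = "provided"`.
#' @return A tibble with `x_px`, `y_px`, `method`.
#' @export
estimate_center <- function(frame,
                            method = c("intensity_centroid", "refined",
                                       "provided"),
                            center = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  method <- match.arg(method)
  if (method == "provided") {
    if (is.null(center) || length(center) != 2) {
      abort("`center` must be c(x_px, y_px) when method = 'provided'.")
    }
    return(tibble(x_px = center[1], y_px = center[2], method = method))
  }
  total <- sum(frame)
  if (total <= 0) abort("Cannot estimate a centre on an all-zero frame.")
  xs <- matrix(seq_len(ncol(frame)) - 0.5, nrow(frame), ncol(frame), byrow = TRUE)
  ys <- matrix(seq_len(nrow(frame)) - 0.5, nrow(frame), ncol(frame))
  cx <- sum(frame * xs) / total
  cy <- sum(frame * ys) / total
  if (method == "intensity_centroid") {
    return(tibble(x_px = cx, y_px = cy, method = method))
  }
  refine_center_crest(frame, cx, cy)
}

# Iterative crest circle fit. From the current centre estimate, the annulus
# crest is the set of pixels in the profile's peak band whose intensity
# exceeds the half-maximum level; angular sectors carrying little crest
# weight are dropped (they are gaps or background), and a circle is fitted
# to the remainder by Gauss-Newton on the intensity-weighted radial
# residuals. Because the crest lies exactly on a circle around the true
# centre, the fit is unbiased for arbitrary arc fractions, which a profile
# sharpness search is not (circles osculating a partial arc can look
# spuriously sharp).
refine_center_crest <- function(frame, cx, cy, n_iter = 4, n_sectors = 90) {
  mpp <- frame_calibration(frame)
  xs <- matrix(seq_len(ncol(frame)) - 0.5, nrow(frame), ncol(frame), byrow = TRUE)
  ys <- matrix(seq_len(nrow(frame)) - 0.5, nrow(frame), ncol(frame))
  m <- as_plain_matrix(frame)
  clamp <- function(ct) pmin(pmax(ct, 2), c(ncol(frame) - 2, nrow(frame) - 2))
  c0 <- clamp(c(cx, cy))
  for (it in seq_len(n_iter)) {
    p <- radial_profile(frame, center = c0)
    pk <- profile_peak(p, refine = FALSE)
    if (pk$no_peak) break
    fw <- profile_fwhm(p, peak = pk)
    band <- max(fw$thickness_um, 25 * mpp, na.rm = TRUE)
    d <- sqrt(((xs - c0[1]) * mpp)^2 + ((ys - c0[2]) * mpp)^2)
    sel <- abs(d - pk$peak_radius_um) <= band
    w <- pmax(m[sel] - fw$half_level, 0)
    keep <- w > 0
    if (sum(keep) < 30) break
    X <- (xs[sel])[keep]; Y <- (ys[sel])[keep]; W <- w[keep]
    theta <- atan2(Y - c0[2], X - c0[1]) %% (2 * pi)
    sec <- floor(theta / (2 * pi / n_sectors)) + 1
    secw <- tapply(W, sec, sum)
    good <- as.integer(names(secw))[secw > 0.25 * median(secw)]
    k2 <- sec %in% good
    X <- X[k2]; Y <- Y[k2]; W <- W[k2]
    cxy <- c0
    di <- sqrt((X - cxy[1])^2 + (Y - cxy[2])^2)
    R <- sum(W * di) / sum(W)
    for (gn in seq_len(20)) {
      di <- pmax(sqrt((X - cxy[1])^2 + (Y - cxy[2])^2), 1e-9)
      J <- cbind((cxy[1] - X) / di, (cxy[2] - Y) / di, -1)
      res <- di - R
      sol <- tryCatch(solve(crossprod(J, W * J), -crossprod(J, W * res)),
                      error = function(e) rep(0, 3))
      nrm <- sqrt(sum(sol[1:2]^2))
      if (nrm > 30) sol <- sol * (30 / nrm) # damp large steps
      cxy <- clamp(cxy + sol[1:2])
      R <- R + sol[3]
      if (sqrt(sum(sol[1:2]^2)) < 0.01) break
    }
    if (sqrt(sum((cxy - c0)^2)) < 0.05) { c0 <- cxy; break }
    c0 <- cxy
  }
  tibble(x_px = c0[1], y_px = c0[2], method = "refined")
}

#' Compute the radial intensity profile of a frame
#'
#' Every pixel at distance `d < r_max_um` from the centre contributes exactly
#' once to the bin `floor(d / bin_width_um)`. With `aggregation = "sum"` the
#' per-bin total intensity is stored (the integrated signal); with `"mean"`
#' (the default) the total is divided by the per-bin pixel count, giving a
#' coverage-normalised profile. Bins that extend past the image borders
#' simply collect fewer pixels, visible in `n_pixels`.
#'
#' @param frame An [image_frame()].
#' @param center A centre tibble from [estimate_center()], or a numeric pair
#'   `c(x_px, y_px)`; `NULL` (default) uses the intensity centroid.
#' @param r_max_um Maximum radius; default reaches the nearest image border
#'   so every default bin is fully covered.
#' @param bin_width_um Radial bin width, um; default one pixel. Must be at
#'   least the pixel size.
#' @param aggregation `"mean"` or `"sum"`.
#' @return A `radial_profile`: a tibble with columns `radius_um` (bin
#'   centres), `value`, `n_pixels`, carrying the centre, bin width,
#'   aggregation and calibration as attributes.
#' @export
radial_profile <- function(frame, center = NULL, r_max_um = NULL,
                           bin_width_um = NULL,
                           aggregation = c("mean", "sum")) {
  stopifnot(inherits(frame, "image_frame"))
  aggregation <- match.arg(aggregation)
  mpp <- frame_calibration(frame)
  if (is.null(center)) center <- estimate_center(frame, "intensity_centroid")
  if (is.data.frame(center)) center <- c(center$x_px[1], center$y_px[1])
  if (center[1] < 0 || center[1] > ncol(frame) ||
      center[2] < 0 || center[2] > nrow(frame)) {
    abort("`center` lies outside the image.")
  }
  if (is.null(bin_width_um)) bin_width_um <- mpp
  if (bin_width_um < mpp) abort("`bin_width_um` must be at least one pixel.")
  if (is.null(r_max_um)) {
    r_max_um <- min(center[1], ncol(frame) - center[1],
                    center[2], nrow(frame) - center[2]) * mpp
  }
  if (r_max_um <= bin_width_um) abort("`r_max_um` is too small for the bin width.")

  xs <- (seq_len(ncol(frame)) - 0.5) * mpp
  ys <- (seq_len(nrow(frame)) - 0.5) * mpp
  dx <- matrix(xs - center[1] * mpp, nrow(frame), ncol(frame), byrow = TRUE)
  dy <- matrix(ys - center[2] * mpp, nrow(frame), ncol(frame))
  d <- sqrt(dx^2 + dy^2)
  keep <- d < r_max_um
  idx <- floor(d[keep] / bin_width_um) + 1L
  nbins <- as.integer(ceiling(r_max_um / bin_width_um))
  counts <- tabulate(idx, nbins = nbins)
  vals <- as_plain_matrix(frame)[keep]
  sums <- numeric(nbins)
  agg <- rowsum(vals, idx)
  sums[as.integer(rownames(agg))] <- agg

  value <- if (aggregation == "sum") sums else ifelse(counts > 0, sums / counts, 0)
  out <- tibble(
    radius_um = (seq_len(nbins) - 0.5) * bin_width_um,
    value = value,
    n_pixels = counts
  )
  structure(
    out,
    center = center,
    bin_width_um = bin_width_um,
    aggregation = aggregation,
    microns_per_pixel = mpp,
    r_max_um = r_max_um,
    class = c("radial_profile", class(out))
  )
}

#' @export
tidy.radial_profile <- function(x, ...) {
  as_tibble(unclass(x)[c("radius_um", "value", "n_pixels")])
}

profile_aggregation <- function(profile) attr(profile, "aggregation")

#' Locate the radial-profile peak
#'
#' Returns the global maximum of the profile; the coordinate of the peak is
#' the ring's radius. Ties are broken toward the smaller radius and flagged.
#' With `refine = TRUE` a three-point parabolic fit around the maximum
#' sharpens the radius to sub-bin precision (flagged in the output). An
#' all-zero profile yields a `no_peak` record rather than an error.
#'
#' @param profile A [radial_profile()].
#' @param refine Apply parabolic sub-bin refinement (default `TRUE`).
#' @return A tibble with `peak_radius_um`, `peak_value`, `tie`, `refined`,
#'   `no_peak`.
#' @export
profile_peak <- function(profile, refine = TRUE) {
  stopifnot(inherits(profile, "radial_profile"))
  v <- profile$value
  r <- profile$radius_um
  if (length(v) == 0) abort("Empty profile.")
  if (all(v <= 0)) {
    return(tibble(peak_radius_um = NA_real_, peak_value = NA_real_,
                  tie = FALSE, refined = FALSE, no_peak = TRUE))
  }
  m <- max(v)
  hits <- which(v == m)
  i <- hits[1] # tie -> smaller radius
  tie <- length(hits) > 1
  radius <- r[i]
  refined <- FALSE
  if (refine && !tie && i > 1 && i < length(v)) {
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (denom < 0) {
      delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
      if (abs(delta) <= 0.5) {
        radius <- r[i] + delta * attr(profile, "bin_width_um")
        refined <- TRUE
      }
    }
  }
  tibble(peak_radius_um = radius, peak_value = m, tie = tie,
         refined = refined, no_peak = FALSE)
}

#' Full width at half maximum of the profile peak
#'
#' The ring-thickness readout. The half-maximum level is
#' `baseline + (peak - baseline) / 2`; crossing radii are located by linear
#' interpolation between adjacent bins on each side of the peak and the
#' width is their difference. With `baseline = "auto"` (default) the
#' baseline is the median of the profile outside `peak +/- 3 x` an initial
#' half-width guess — a guard against the pedestal the branched background
#' adds;
#' `"zero"` uses a zero baseline. If the half level is never crossed on one
#' side (a truncated ring), the result is flagged `one_sided` and reported
#' as twice the available half-width.
#'
#' @param profile A [radial_profile()].
#' @param peak A [profile_peak()] row; computed if `NULL`.
#' @param baseline `"auto"` or `"zero"`.
#' @return A tibble with `thickness_um`, `baseline`, `half_level`,
#'   `left_um`, `right_um`, `one_sided`.
#' @export
profile_fwhm <- function(profile, peak = NULL, baseline = c("auto", "zero")) {
  stopifnot(inherits(profile, "radial_profile"))
  baseline <- match.arg(baseline)
  if (is.null(peak)) peak <- profile_peak(profile, refine = FALSE)
  if (peak$no_peak) abort("Cannot compute a FWHM without a peak.")
  v <- profile$value
  r <- profile$radius_um
  ip <- which.min(abs(r - peak$peak_radius_um))
  pv <- v[ip]

  cross <- function(level, side) {
    idx <- if (side == "left") rev(seq_len(ip - 1)) else seq(ip + 1, length(v))
    if (ip == 1 && side == "left") return(NA_real_)
    if (ip == length(v) && side == "right") return(NA_real_)
    prev <- ip
    for (k in idx) {
      if (v[k] < level) {
        # linear interpolation between bins k and prev
        return(r[k] + (level - v[k]) / (v[prev] - v[k]) * (r[prev] - r[k]))
      }
      prev <- k
    }
    NA_real_
  }

  # initial half-width guess from the zero-baseline half level
  l0 <- cross(pv / 2, "left")
  r0 <- cross(pv / 2, "right")
  w0 <- if (!is.na(l0) && !is.na(r0)) (r0 - l0) / 2
        else attr(profile, "bin_width_um") * 4

  b <- 0
  if (baseline == "auto") {
    outside <- abs(r - peak$peak_radius_um) > 3 * w0
    if (sum(outside) >= 3) b <- median(v[outside])
  }
  half <- b + (pv - b) / 2
  left <- cross(half, "left")
  right <- cross(half, "right")
  one_sided <- xor(is.na(left), is.na(right))
  thickness <- if (!is.na(left) && !is.na(right)) {
    right - left
  } else if (!is.na(left)) {
    2 * (peak$peak_radius_um - left)
  } else if (!is.na(right)) {
    2 * (right - peak$peak_radius_um)
  } else {
    NA_real_
  }
  tibble(thickness_um = thickness, baseline = b, half_level = half,
         left_um = left, right_um = right, one_sided = one_sided)
}

#' Area under the radial profile
#'
#' Trapezoidal integral of the profile over a radius range; with sum
#' aggregation over the full range this is monotone in the total intensity
#' within the disc, which is what makes the AUC a network-abundance readout.
#'
#' @param profile A [radial_profile()].
#' @param r_min_um,r_max_um Integration range, um; defaults to the full
#'   profile support.
#' @return The integral, in AU x um.
#' @export
profile_auc <- function(profile, r_min_um = NULL, r_max_um = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  r <- profile$radius_um
  v <- profile$value
  if (is.null(r_min_um)) r_min_um <- min(r)
  if (is.null(r_max_um)) r_max_um <- max(r)
  keep <- r >= r_min_um & r <= r_max_um
  if (sum(keep) < 2) abort("The AUC range must contain at least two bins.")
  pracma::trapz(r[keep], v[keep])
}
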