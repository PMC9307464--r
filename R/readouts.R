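# Biological readouts derived from the radial profile: ring diameter,
# thickness, AUC, peak intensity, and two continuity measures — the peak
# intensity proxy (the field's readout) and a direct angular occupancy index
# that serves as its independent check.

#' Measure a ring-patterned frame end to end
#'
#' Runs centre estimation, radial profiling, peak and FWHM extraction, AUC,
#' and both continuity measures, and assembles one measurement record. When
#' the profile shows no characteristic peak — the signature of an
#' unpatterned, randomly organised network — a `no_peak` record with absent
#' (`NA`) readouts is returned; readouts are never fabricated.
#'
#' Whether the profile shows a characteristic peak at all is decided on a
#' smoothed copy of the profile (running mean over `smooth_um`): a real
#' annulus is hundreds of micrometres wide, whereas a stray filament crossing
#' a circle tangentially only spikes a few neighbouring bins, so smoothing
#' suppresses the latter. The smoothed peak must rise above the smoothed
#' profile's lower quartile (a baseline the annulus band itself cannot
#' contaminate, unlike the median) by at least `peak_prominence` times that
#' quartile. All geometric
#' readouts are still taken from the unsmoothed profile. Innermost bins
#' holding fewer than `min_bin_pixels` pixels are zeroed before peak
#' finding; their means are statistically unstable.
#'
#' @param frame A calibrated [image_frame()].
#' @param center_method Passed to [estimate_center()]; use `"refined"`
#'   for visibly broken rings.
#' @param center Optional explicit centre `c(x_px, y_px)` (implies
#'   `center_method = "provided"`).
#' @param bin_width_um Radial bin width; default one pixel.
#' @param baseline FWHM baseline rule, `"auto"` or `"zero"`.
#' @param peak_prominence Minimum (smoothed peak - baseline) / baseline for
#'   a characteristic peak, with the lower quartile as baseline; default 5.
#' @param smooth_um Width of the running-mean window used only for the
#'   peak-existence decision, um; default 75.
#' @param min_bin_pixels Minimum pixels per bin for peak finding; default 8.
#' @param day Day label; defaults to the frame's own label.
#'
#' @return A one-row tibble: `day`, `diameter_um`, `thickness_um`,
#'   `peak_radius_um`, `peak_intensity`, `auc`, `continuity_proxy`,
#'   `continuity_index`, `center_x_px`, `center_y_px`, `no_peak`, `flags`.
#'   `diameter_um` is exactly twice `peak_radius_um`.
#' @export
measure_ring <- function(frame,
                         center_method = c("intensity_centroid", "refined",
                                           "provided"),
                         center = NULL,
                         bin_width_um = NULL,
                         baseline = c("auto", "zero"),
                         peak_prominence = 5,
                         smooth_um = 75,
                         min_bin_pixels = 8,
                         day = attr(frame, "day")) {
  stopifnot(inherits(frame, "image_frame"))
  center_method <- match.arg(center_method)
  baseline <- match.arg(baseline)
  if (!is.null(center)) center_method <- "provided"
  ctr <- estimate_center(frame, center_method, center = center)
  day <- if (is.null(day) || length(day) == 0) NA_integer_ else as.integer(day)

  prof <- radial_profile(frame, center = ctr, bin_width_um = bin_width_um,
                         aggregation = "mean")
  prof$value[prof$n_pixels < min_bin_pixels] <- 0
  pk <- profile_peak(prof)

  no_peak_record <- function(flag) {
    tibble(
      day = day, diameter_um = NA_real_, thickness_um = NA_real_,
      peak_radius_um = NA_real_, peak_intensity = NA_real_, auc = NA_real_,
      continuity_proxy = NA_real_, continuity_index = NA_real_,
      center_x_px = ctr$x_px, center_y_px = ctr$y_px,
      no_peak = TRUE, flags = flag
    )
  }
  if (pk$no_peak) return(no_peak_record("no_peak"))
  k <- max(1L, round(smooth_um / attr(prof, "bin_width_um")))
  smoothed <- as.numeric(stats::filter(prof$value, rep(1 / k, k), sides = 2))
  smoothed[is.na(smoothed)] <- 0
  base <- quantile(smoothed[prof$n_pixels >= min_bin_pixels], 0.25,
                   names = FALSE)
  prominent <- (max(smoothed) - base) > peak_prominence * max(base, 1e-9) &&
    pk$peak_value > 0
  if (!prominent) return(no_peak_record("no_peak"))

  fw <- profile_fwhm(prof, peak = pk, baseline = baseline)
  auc <- profile_auc(prof)
  sprof <- radial_profile(frame, center = ctr, bin_width_um = bin_width_um,
                          aggregation = "sum")
  proxy <- continuity_peak_proxy(sprof)
  ci <- if (!is.na(fw$thickness_um)) {
    tryCatch(
      continuity_index(frame, center = ctr,
                       radius_um = pk$peak_radius_um,
                       thickness_um = fw$thickness_um),
      error = function(e) NA_real_
    )
  } else {
    NA_real_
  }

  flags <- c(
    if (pk$tie) "tie",
    if (isTRUE(fw$one_sided)) "one_sided_fwhm"
  )
  tibble(
    day = day,
    diameter_um = 2 * pk$peak_radius_um,
    thickness_um = fw$thickness_um,
    peak_radius_um = pk$peak_radius_um,
    peak_intensity = pk$peak_value,
    auc = auc,
    continuity_proxy = proxy,
    continuity_index = ci,
    center_x_px = ctr$x_px, center_y_px = ctr$y_px,
    no_peak = FALSE,
    flags = paste(flags, collapse = "|")
  )
}

#' Measure a list of frames into one table
#'
#' @param frames A list of [image_frame()]s (e.g. a timecourse's `frames`).
#' @param ... Passed to [measure_ring()].
#' @return A tibble with one row per frame.
#' @export
measure_rings <- function(frames, ...) {
  purrr::map_dfr(frames, measure_ring, ...)
}

#' Peak-intensity continuity proxy
#'
#' The sum-aggregated radial-profile peak value. With sum aggregation the
#' peak bin totals the intensity of every lit pixel on the ring's crest, so
#' for fixed geometry and amplitude it is directly proportional to the
#' fraction of the circle that is present — this is what makes the peak
#' intensity usable as a ring-continuity readout. It equally scales with
#' amplitude, a confounder the angular occupancy index
#' ([continuity_index()]) does not share.
#'
#' @param profile A sum-aggregated [radial_profile()].
#' @return The peak bin value (AU), or `NA` if the profile has no peak.
#' @export
continuity_peak_proxy <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  if (profile_aggregation(profile) != "sum") {
    abort("The continuity proxy is defined on a sum-aggregated profile.")
  }
  pk <- profile_peak(profile, refine = FALSE)
  if (pk$no_peak) return(NA_real_)
  pk$peak_value
}

#' Angular-occupancy continuity index
#'
#' Direct continuity measurement: the fraction of angular bins (default 360
#' one-degree bins) whose mean intensity inside the annulus
#' `radius +/- thickness / 2` exceeds a threshold. The default threshold is
#' Otsu on the annulus pixels, capped at half the annulus's robust maximum
#' (95th percentile) — the cap guards the fully continuous ring, where the
#' intensity histogram is unimodal and an uncapped Otsu split would darken
#' arbitrary bins.
#'
#' @param frame An [image_frame()].
#' @param center Centre tibble or `c(x_px, y_px)`.
#' @param radius_um,thickness_um Annulus geometry (from a ring measurement).
#' @param n_bins Number of angular bins (default 360).
#' @param threshold `"otsu"` (default) or an explicit intensity value.
#' @return The occupied fraction, in \[0, 1\].
#' @export
continuity_index <- function(frame, center, radius_um, thickness_um,
                             n_bins = 360, threshold = "otsu") {
  stopifnot(inherits(frame, "image_frame"))
  mpp <- frame_calibration(frame)
  if (is.data.frame(center)) center <- c(center$x_px[1], center$y_px[1])
  if (radius_um + thickness_um / 2 >
      (min(center[1], ncol(frame) - center[1],
           center[2], nrow(frame) - center[2])) * mpp) {
    abort("The annulus extends outside the image.")
  }
  xs <- (seq_len(ncol(frame)) - 0.5) * mpp
  ys <- (seq_len(nrow(frame)) - 0.5) * mpp
  dx <- matrix(xs - center[1] * mpp, nrow(frame), ncol(frame), byrow = TRUE)
  dy <- matrix(ys - center[2] * mpp, nrow(frame), ncol(frame))
  d <- sqrt(dx^2 + dy^2)
  inside <- abs(d - radius_um) <= thickness_um / 2
  if (!any(inside)) abort("The annulus contains no pixels.")
  vals <- as_plain_matrix(frame)[inside]
  theta <- atan2(dy, dx)[inside] %% (2 * pi)
  bin <- pmin(floor(theta / (2 * pi / n_bins)) + 1L, n_bins)
  means <- rep(NA_real_, n_bins)
  agg <- rowsum(vals, bin) / tabulate(bin, n_bins)[sort(unique(bin))]
  means[as.integer(rownames(agg))] <- agg

  thr <- if (identical(threshold, "otsu")) {
    rng <- range(vals)
    ot <- if (diff(rng) > 0) {
      EBImage::otsu(matrix(vals, ncol = 1), range = rng, levels = 256)
    } else {
      rng[1]
    }
    min(ot, 0.5 * quantile(vals, 0.95, names = FALSE))
  } else {
    as.numeric(threshold)
  }
  mean(means > thr, na.rm = TRUE)
}

#' Compare a measured day series against a baseline day
#'
#' Per-day ratios of the AUC and of the continuity peak proxy relative to a
#' baseline day, with a flag for days that fall below baseline. This is the
#' scale on which longitudinal ring changes are reported, since absolute AU
#' depend on unrecorded acquisition gain.
#'
#' @param measurements A tibble of [measure_ring()] rows with a `day` column.
#' @param baseline_day Integer baseline day (default 0).
#' @return A tibble with `day`, `auc_ratio`, `proxy_ratio`,
#'   `below_baseline`.
#' @export
compare_days <- function(measurements, baseline_day = 0L) {
  if (!baseline_day %in% measurements$day) {
    abort(sprintf("Baseline day %d is not present in the series.", baseline_day))
  }
  base <- measurements[measurements$day == baseline_day, ]
  if (nrow(base) != 1 || base$no_peak) {
    abort("The baseline day must hold exactly one measurable (peaked) record.")
  }
  out <- measurements |>
    dplyr::transmute(
      day = .data$day,
      auc_ratio = .data$auc / base$auc,
      proxy_ratio = .data$continuity_proxy / base$continuity_proxy
    ) |>
    dplyr::mutate(below_baseline = .data$auc_ratio < 1 | .data$proxy_ratio < 1)
  structure(out, baseline_day = baseline_day,
            class = c("day_comparison", class(out)))
}

#' Replicate summary of ring measurements
#'
#' Mean, SD (n - 1 denominator) and n per readout across a replicate table,
#' alongside the per-replicate values.
#'
#' @param measurements Tibble of [measure_ring()] rows.
#' @return A tibble with `readout`, `n`, `mean`, `sd`.
#' @export
replicate_summary <- function(measurements) {
  usable <- measurements[!measurements$no_peak, ]
  if (nrow(usable) < 2) abort("At least two measurable replicates are required.")
  usable |>
    dplyr::select("diameter_um", "thickness_um", "peak_intensity", "auc",
                  "continuity_index") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "readout") |>
    dplyr::group_by(.data$readout) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}
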