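# Shared fixtures: the full 3.58 mm field rendered at coarser pixel sizes so
# unit tests stay fast while geometry (ring 1781 um / 416 um) is unchanged.

# 448 px @ 8 um/px: the workhorse test field
test_spec <- function(...) {
  ring_spec(image_size_px = c(448L, 448L), microns_per_pixel = 8, ...)
}

# 128 px @ 28 um/px: very fast field for sampling-heavy tests
small_spec <- function(...) {
  ring_spec(image_size_px = c(128L, 128L), microns_per_pixel = 28, ...)
}

noiseless <- function() noise_spec(0, 0, 0)

# independent brute-force radial accumulation (double loop over pixels)
naive_radial_profile <- function(frame, center, r_max_um, bin_width_um,
                                 aggregation = "mean") {
  mpp <- attr(frame, "microns_per_pixel")
  nbins <- as.integer(ceiling(r_max_um / bin_width_um))
  sums <- numeric(nbins)
  counts <- integer(nbins)
  for (j in seq_len(ncol(frame))) {     # column-major like the image vector
    for (i in seq_len(nrow(frame))) {
      d <- sqrt(((j - 0.5) - center[1])^2 + ((i - 0.5) - center[2])^2) * mpp
      if (d < r_max_um) {
        b <- floor(d / bin_width_um) + 1L
        sums[b] <- sums[b] + frame[i, j]
        counts[b] <- counts[b] + 1L
      }
    }
  }
  value <- if (aggregation == "sum") sums else ifelse(counts > 0, sums / counts, 0)
  list(value = value, n_pixels = counts)
}

# build a radial_profile object with prescribed values on a uniform grid,
# for peak/FWHM unit tests that need exact analytic shapes
analytic_profile <- function(values, bin_width_um = 1, aggregation = "mean") {
  n <- length(values)
  out <- tibble::tibble(
    radius_um = (seq_len(n) - 0.5) * bin_width_um,
    value = values,
    n_pixels = rep(100L, n)
  )
  structure(
    out,
    center = c(0, 0),
    bin_width_um = bin_width_um,
    aggregation = aggregation,
    microns_per_pixel = bin_width_um,
    r_max_um = n * bin_width_um,
    class = c("radial_profile", class(out))
  )
}
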