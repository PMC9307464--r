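# The radial profile statistic: oracle equality, conservation laws, centre
# estimation, peak, FWHM, AUC.

test_that("profiles match a naive double-loop accumulation bit-for-bit", {
  set.seed(7)
  for (n in c(17, 40, 64)) {
    px <- matrix(sample(0:65535, n * n, replace = TRUE), n, n)
    frame <- image_frame(px, microns_per_pixel = 2)
    center <- c(n / 2 + runif(1, -3, 3), n / 2 + runif(1, -3, 3))
    for (agg in c("sum", "mean")) {
      p <- radial_profile(frame, center = center, r_max_um = n * 0.8,
                          bin_width_um = 3, aggregation = agg)
      o <- naive_radial_profile(frame, center, r_max_um = n * 0.8,
                                bin_width_um = 3, aggregation = agg)
      expect_identical(p$value, o$value)
      expect_identical(p$n_pixels, o$n_pixels)
    }
  }
})

test_that("every pixel within r_max lands in exactly one bin", {
  spec <- test_spec(seed = 2L)
  frame <- generate_ring_image(spec, noise_spec(seed = 2L))$frame
  center <- c(230, 220)
  r_max <- 1500
  p <- radial_profile(frame, center = center, r_max_um = r_max)
  xs <- (seq_len(ncol(frame)) - 0.5 - center[1]) * 8
  ys <- (seq_len(nrow(frame)) - 0.5 - center[2]) * 8
  d <- sqrt(outer(ys^2, xs^2, `+`))
  expect_identical(sum(p$n_pixels), sum(d < r_max))
})

test_that("sum and mean aggregations are consistent per bin", {
  frame <- generate_ring_image(test_spec(seed = 3L), noise_spec(seed = 3L))$frame
  ps <- radial_profile(frame, center = c(224, 224), aggregation = "sum")
  pm <- radial_profile(frame, center = c(224, 224), aggregation = "mean")
  expect_equal(ps$value, pm$value * pm$n_pixels)
})

test_that("a uniform image gives a flat mean profile and count-shaped sums", {
  frame <- image_frame(matrix(1, 64, 64), microns_per_pixel = 4)
  pm <- radial_profile(frame, center = c(32, 32), aggregation = "mean")
  expect_true(all(pm$value[pm$n_pixels > 0] == 1))
  ps <- radial_profile(frame, center = c(32, 32), aggregation = "sum")
  expect_identical(ps$value, as.numeric(ps$n_pixels))
})

test_that("peak radius and AUC are invariant under 90-degree rotation", {
  frame <- generate_ring_image(test_spec(seed = 4L, center_offset_um = c(160, -80)),
                               noise_spec(seed = 4L))$frame
  rot <- image_frame(t(unclass(frame))[ncol(frame):1, ], microns_per_pixel = 8)
  p1 <- radial_profile(frame)
  p2 <- radial_profile(rot)
  pk1 <- profile_peak(p1)
  pk2 <- profile_peak(p2)
  expect_lt(abs(pk1$peak_radius_um - pk2$peak_radius_um),
            attr(p1, "bin_width_um"))
  expect_lt(abs(profile_auc(p1) / profile_auc(p2) - 1), 0.01)
})

test_that("centre estimation recovers known centres", {
  centred <- generate_ring_image(test_spec(n_branches = 0L, seed = 5L), noiseless())
  c1 <- estimate_center(centred$frame)
  expect_lt(abs(c1$x_px - 224), 1)
  expect_lt(abs(c1$y_px - 224), 1)

  off <- generate_ring_image(test_spec(n_branches = 0L, seed = 5L,
                                       center_offset_um = c(50 * 8, -30 * 8)),
                             noiseless())
  c2 <- estimate_center(off$frame)
  expect_lt(sqrt((c2$x_px - 274)^2 + (c2$y_px - 194)^2), 2)

  expect_error(estimate_center(image_frame(matrix(0, 8, 8), 4)), "all-zero")
})

test_that("refined centre recovers a half ring the centroid cannot", {
  half <- generate_ring_image(test_spec(n_branches = 0L, seed = 6L,
                                        arc_fraction = 0.5),
                              noiseless())
  centroid <- estimate_center(half$frame, "intensity_centroid")
  bias <- sqrt((centroid$x_px - 224)^2 + (centroid$y_px - 224)^2)
  expect_gt(bias, 20) # the centroid is pulled toward the arc
  refined <- estimate_center(half$frame, "refined")
  err <- sqrt((refined$x_px - 224)^2 + (refined$y_px - 224)^2)
  expect_lt(err, 5)
})

test_that("peak location follows the stated tie and refinement rules", {
  mono <- analytic_profile(c(10, 8, 6, 4, 2))
  pk <- profile_peak(mono)
  expect_equal(pk$peak_radius_um, 0.5)
  expect_false(pk$tie)

  tied <- analytic_profile(c(1, 5, 2, 5, 1))
  pk2 <- profile_peak(tied)
  expect_true(pk2$tie)
  expect_equal(pk2$peak_radius_um, 1.5) # smaller radius wins

  r <- (seq_len(101) - 0.5)
  gauss <- analytic_profile(exp(-(r - 50.2)^2 / (2 * 9^2)))
  pk3 <- profile_peak(gauss)
  expect_true(pk3$refined)
  expect_lt(abs(pk3$peak_radius_um - 50.2), 0.1)

  zero <- analytic_profile(rep(0, 10))
  expect_true(profile_peak(zero)$no_peak)
})

test_that("FWHM matches the Gaussian closed form and the stated edge rules", {
  sigma <- 9
  r <- (seq_len(121) - 0.5)
  gauss <- analytic_profile(exp(-(r - 60)^2 / (2 * sigma^2)))
  fw <- profile_fwhm(gauss, baseline = "zero")
  expect_lt(abs(fw$thickness_um / (2.3548 * sigma) - 1), 0.02)
  expect_false(fw$one_sided)

  # pedestal: the auto baseline removes it, a zero baseline does not
  ped <- analytic_profile(0.5 + exp(-(r - 60)^2 / (2 * sigma^2)))
  fw_auto <- profile_fwhm(ped, baseline = "auto")
  expect_lt(abs(fw_auto$thickness_um / (2.3548 * sigma) - 1), 0.05)
  fw_zero <- profile_fwhm(ped, baseline = "zero")
  expect_gt(fw_zero$thickness_um, fw_auto$thickness_um)

  # truncated on the left: one-sided flag and doubled half-width
  trunc <- analytic_profile(exp(-(r - 5)^2 / (2 * 20^2)))
  fw_t <- profile_fwhm(trunc, baseline = "zero")
  expect_true(fw_t$one_sided)
  expect_equal(fw_t$thickness_um,
               2 * (fw_t$right_um - profile_peak(trunc, refine = FALSE)$peak_radius_um))
})

test_that("FWHM of a rectangular annulus is the annulus width", {
  n <- 200
  mpp <- 4
  xs <- (seq_len(n) - 0.5 - n / 2) * mpp
  d <- sqrt(outer(xs^2, xs^2, `+`))
  w <- 80
  px <- ifelse(abs(d - 250) <= w / 2, 1000, 0)
  frame <- image_frame(px, microns_per_pixel = mpp)
  p <- radial_profile(frame, center = c(n / 2, n / 2))
  fw <- profile_fwhm(p, baseline = "zero")
  expect_gte(fw$thickness_um, w - mpp)
  expect_lte(fw$thickness_um, w + mpp)
})

test_that("AUC behaves like a trapezoidal integral", {
  zero <- analytic_profile(rep(0, 12))
  expect_equal(profile_auc(zero), 0)

  const <- analytic_profile(rep(3, 51))
  expect_equal(profile_auc(const), 3 * 50) # c x L over the bin-centre span

  f1 <- generate_ring_image(test_spec(n_branches = 0L, seed = 8L), noiseless())$frame
  f2 <- generate_ring_image(test_spec(n_branches = 0L, seed = 8L,
                                      ring_amplitude = 40000), noiseless())$frame
  a1 <- profile_auc(radial_profile(f1, center = c(224, 224)))
  a2 <- profile_auc(radial_profile(f2, center = c(224, 224)))
  expect_lt(abs(a2 / a1 - 2), 0.01 * 2)

  expect_error(profile_auc(const, r_min_um = 10, r_max_um = 10.2),
               "at least two bins")
})

test_that("invalid centres and bin widths are rejected", {
  frame <- image_frame(matrix(1, 32, 32), 4)
  expect_error(radial_profile(frame, center = c(100, 10)), "outside")
  expect_error(radial_profile(frame, center = c(16, 16), bin_width_um = 1),
               "at least one pixel")
})
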