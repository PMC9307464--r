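# The synthetic generator: determinism, mass linearity, geometry checks,
# programmed dynamics, replicate sampling.

test_that("identical specs and seeds reproduce images bit-for-bit", {
  spec <- small_spec(seed = 42L)
  nz <- noise_spec(seed = 9L)
  a <- generate_ring_image(spec, nz)
  b <- generate_ring_image(spec, nz)
  expect_identical(unclass(a$frame), unclass(b$frame))
  expect_identical(a$truth, b$truth)

  ra <- generate_network_image(spec, nz)
  rb <- generate_network_image(spec, nz)
  expect_identical(unclass(ra$frame), unclass(rb$frame))

  pa <- generate_replicates(2, spec, noise = nz)
  pb <- generate_replicates(2, spec, noise = nz)
  expect_identical(pa$truth, pb$truth)
  expect_identical(unclass(pa$sims[[2]]$frame), unclass(pb$sims[[2]]$frame))
})

test_that("zero amplitudes give all-zero images", {
  spec <- small_spec(ring_amplitude = 0, background_amplitude = 0, seed = 1L)
  s <- generate_ring_image(spec, noiseless())
  expect_true(all(s$frame == 0))
  expect_equal(s$truth$area_um2, 0)
  n <- generate_network_image(small_spec(n_branches = 0L, background_amplitude = 0),
                              noiseless())
  expect_true(all(n$frame == 0))
})

test_that("a ring that does not fit in the field is rejected", {
  expect_error(
    ring_spec(image_size_px = c(128L, 128L), microns_per_pixel = 8,
              ring_diameter_um = 1781),
    class = "ringprofiler_geometry_error"
  )
  expect_error(
    test_spec(center_offset_um = c(600, 0)),
    class = "ringprofiler_geometry_error"
  )
})

test_that("the noiseless annulus peaks at the true radius", {
  spec <- test_spec(n_branches = 0L, seed = 2L)
  s <- generate_ring_image(spec, noiseless())
  p <- radial_profile(s$frame, center = c(224, 224))
  pk <- profile_peak(p, refine = FALSE)
  expect_lt(abs(pk$peak_radius_um - 1781 / 2), attr(p, "bin_width_um"))
})

test_that("total ring intensity is linear in amplitude and arc fraction", {
  base <- test_spec(n_branches = 0L, seed = 3L)
  full <- generate_ring_image(base, noiseless())
  half_spec <- test_spec(n_branches = 0L, seed = 3L, arc_fraction = 0.5)
  half <- generate_ring_image(half_spec, noiseless())
  expect_lt(abs(sum(half$frame) / sum(full$frame) - 0.5), 0.01 * 0.5)

  bright <- test_spec(n_branches = 0L, seed = 3L, ring_amplitude = 40000)
  expect_equal(sum(generate_ring_image(bright, noiseless())$frame),
               2 * sum(full$frame), tolerance = 1e-10)

  quarter <- generate_ring_image(
    test_spec(n_branches = 0L, seed = 3L, arc_fraction = 0.25), noiseless())
  expect_lt(abs(sum(quarter$frame) / sum(full$frame) - 0.25), 0.01 * 0.25)
})

test_that("an explicit inconsistent gap layout is rejected", {
  expect_error(
    generate_ring_image(
      test_spec(arc_fraction = 0.5, gap_layout = list(c(0, pi / 4))),
      noiseless()
    ),
    "inconsistent"
  )
})

test_that("doubling the filament count roughly doubles the foreground", {
  few <- generate_network_image(test_spec(n_branches = 25L, seed = 5L), noiseless())
  many <- generate_network_image(test_spec(n_branches = 50L, seed = 5L), noiseless())
  ratio <- many$truth$area_um2 / few$truth$area_um2
  expect_gt(ratio, 1.6) # overlap makes it slightly sub-linear
  expect_lt(ratio, 2.1)
})

test_that("ground-truth area is stable under 2x resolution change", {
  coarse <- generate_ring_image(test_spec(seed = 6L), noiseless())
  fine <- generate_ring_image(
    ring_spec(image_size_px = c(896L, 896L), microns_per_pixel = 4, seed = 6L),
    noiseless()
  )
  expect_lt(abs(fine$truth$area_um2 / coarse$truth$area_um2 - 1), 0.02)
})

test_that("timecourse areas follow the programmed multipliers", {
  spec <- test_spec(seed = 7L)
  flat <- dynamics_spec(days = -1:1)
  tc_flat <- generate_timecourse(spec, noiseless(), flat)
  expect_true(all(tc_flat$truth$area_um2 == tc_flat$truth$area_um2[1]))

  dyn <- dynamics_spec(
    days = c(-1L, 2L, 4L),
    area_multiplier = c(1, 1.45, 1),
    )
  tc <- generate_timecourse(spec, noiseless(), dyn)
  ratios <- tc$truth$area_um2 / tc$truth$area_um2[1]
  expect_gte(ratios[2], 1.43)
  expect_lte(ratios[2], 1.47)
  expect_lt(abs(ratios[3] - 1), 0.02)
  expect_equal(tc$truth$day, c(-1L, 2L, 4L))
})

test_that("unreachable area multipliers raise an error", {
  spec <- small_spec(seed = 8L)
  dyn <- dynamics_spec(days = c(-1L, 1L), area_multiplier = c(1, 50))
  expect_error(generate_timecourse(spec, noiseless(), dyn), "unreachable")
})

test_that("dynamics specs are validated", {
  expect_error(dynamics_spec(days = 0:2), "day -1")
  expect_error(dynamics_spec(days = c(-1, 0), area_multiplier = c(1.2, 1)),
               "baseline")
  expect_error(dynamics_spec(days = c(-1, 0), continuity = c(1, 0)), "continuity")
})

test_that("replicate sets sample the stated normal laws", {
  spec <- small_spec(seed = 10L)
  fixed <- generate_replicates(3, spec, diameter_sd = 0, thickness_sd = 0,
                               noise = noiseless())
  expect_true(all(fixed$truth$radius_um == spec$ring_diameter_um / 2))
  expect_true(all(fixed$truth$thickness_um == spec$ring_thickness_um))

  reps <- generate_replicates(100, spec, diameter_sd = 142, thickness_sd = 124,
                              noise = noiseless())
  se <- 142 / sqrt(100)
  expect_lt(abs(mean(2 * reps$truth$radius_um) - 1781), 3 * se)
  expect_error(generate_replicates(1, spec), ">= 2")
})
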