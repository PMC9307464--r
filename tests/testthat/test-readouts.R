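# Ring readouts: end-to-end measurement, continuity proxy vs angular
# occupancy, day-series comparisons, replicate summaries.

test_that("a noiseless default ring is measured to its true geometry", {
  s <- generate_ring_image(test_spec(seed = 1L), noiseless())
  m <- measure_ring(s$frame)
  expect_false(m$no_peak)
  expect_lt(abs(m$diameter_um / 1781 - 1), 0.02)
  expect_lt(abs(m$thickness_um / 416 - 1), 0.05)
  expect_equal(m$diameter_um, 2 * m$peak_radius_um)
})

test_that("randomly organised networks yield a no-peak record, never readouts", {
  r <- generate_network_image(test_spec(seed = 2L), noise_spec(seed = 2L))
  m <- measure_ring(r$frame)
  expect_true(m$no_peak)
  expect_true(is.na(m$diameter_um))
  expect_true(is.na(m$auc))
  expect_true(is.na(m$continuity_index))
  expect_match(m$flags, "no_peak")
})

test_that("measured mean diameter tracks the replicate sampling law", {
  spec <- ring_spec(image_size_px = c(224L, 224L), microns_per_pixel = 16,
                    seed = 3L, n_branches = 10L)
  reps <- generate_replicates(12, spec, diameter_sd = 142, thickness_sd = 60,
                              noise = noiseless())
  meas <- measure_rings(lapply(reps$sims, `[[`, "frame"))
  expect_true(all(!meas$no_peak))
  se <- 142 / sqrt(12)
  expect_lt(abs(mean(meas$diameter_um) - 1781), 3 * se + 20)
  summ <- replicate_summary(meas)
  expect_setequal(
    summ$readout,
    c("diameter_um", "thickness_um", "peak_intensity", "auc", "continuity_index")
  )
  expect_equal(summ$n[summ$readout == "diameter_um"], 12)
})

test_that("the sum-profile peak is proportional to the arc fraction", {
  full <- generate_ring_image(test_spec(n_branches = 0L, seed = 4L), noiseless())
  center <- c(224, 224)
  p_full <- radial_profile(full$frame, center = center, aggregation = "sum")
  proxies <- vapply(c(0.25, 0.5, 0.75), function(af) {
    s <- generate_ring_image(test_spec(n_branches = 0L, seed = 4L,
                                       arc_fraction = af), noiseless())
    continuity_peak_proxy(radial_profile(s$frame, center = center,
                                         aggregation = "sum"))
  }, numeric(1))
  ref <- continuity_peak_proxy(p_full)
  expect_lt(abs(proxies[2] / ref - 0.5), 0.02 * 0.5)
  expect_true(all(diff(c(proxies, ref)) > 0)) # strictly increasing in arc

  # amplitude is a confounder: doubling it doubles the proxy at fixed arc
  bright <- generate_ring_image(test_spec(n_branches = 0L, seed = 4L,
                                          ring_amplitude = 40000), noiseless())
  p_bright <- radial_profile(bright$frame, center = center, aggregation = "sum")
  expect_equal(continuity_peak_proxy(p_bright) / ref, 2, tolerance = 1e-6)

  expect_error(continuity_peak_proxy(radial_profile(full$frame, center = center)),
               "sum-aggregated")
})

test_that("the angular occupancy index measures the lit arc directly", {
  full <- generate_ring_image(test_spec(n_branches = 0L, seed = 5L), noiseless())
  m <- measure_ring(full$frame)
  expect_gte(m$continuity_index, 0.99)

  half <- generate_ring_image(test_spec(n_branches = 0L, seed = 5L,
                                        arc_fraction = 0.5), noiseless())
  ci <- continuity_index(half$frame, center = c(224, 224),
                         radius_um = 1781 / 2, thickness_um = 416)
  expect_lt(abs(ci - 0.5), 0.02)

  expect_error(
    continuity_index(full$frame, center = c(30, 224), radius_um = 1781 / 2,
                     thickness_um = 416),
    "outside"
  )
})

test_that("peak proxy and angular index agree across an arc sweep", {
  arcs <- seq(0.3, 1, length.out = 8)
  center <- c(224, 224)
  res <- purrr::map_dfr(seq_along(arcs), function(i) {
    s <- generate_ring_image(test_spec(seed = 10L + i, arc_fraction = arcs[i]),
                             noise_spec(seed = 20L + i))
    prof <- radial_profile(s$frame, center = center, aggregation = "sum")
    tibble::tibble(
      proxy = continuity_peak_proxy(prof),
      index = continuity_index(s$frame, center = center,
                               radius_um = 1781 / 2, thickness_um = 416)
    )
  })
  r2 <- summary(lm(proxy ~ index, data = res))$r.squared
  expect_gte(r2, 0.9)
})

test_that("day comparisons are ratios against the baseline day", {
  s <- generate_ring_image(test_spec(seed = 6L), noise_spec(seed = 6L))
  same <- list(`0` = s$frame, `2` = s$frame, `4` = s$frame)
  meas <- measure_rings(same, day = NULL)
  meas$day <- c(0L, 2L, 4L)
  cmp <- compare_days(meas, baseline_day = 0L)
  expect_equal(cmp$auc_ratio, rep(1, 3))
  expect_equal(cmp$proxy_ratio, rep(1, 3))
  expect_false(any(cmp$below_baseline))
  expect_error(compare_days(meas, baseline_day = -1L), "not present")
})

test_that("programmed arc regression drives the proxy ratio below one", {
  center <- c(224, 224)
  d0 <- generate_ring_image(test_spec(seed = 7L), noise_spec(seed = 7L))
  d4 <- generate_ring_image(test_spec(seed = 7L, arc_fraction = 0.6),
                            noise_spec(seed = 8L))
  meas <- dplyr::bind_rows(
    measure_ring(d0$frame, center = center, day = 0L),
    measure_ring(d4$frame, center = center, day = 4L)
  )
  cmp <- compare_days(meas, baseline_day = 0L)
  expect_lt(cmp$proxy_ratio[cmp$day == 4L], 1)
  expect_true(cmp$below_baseline[cmp$day == 4L])
})

test_that("micron readouts survive a resolution change", {
  fine <- generate_ring_image(test_spec(seed = 9L), noiseless())$frame
  coarse <- generate_ring_image(
    ring_spec(image_size_px = c(224L, 224L), microns_per_pixel = 16, seed = 9L),
    noiseless()
  )$frame
  m1 <- measure_ring(fine)
  m2 <- measure_ring(coarse)
  expect_lt(abs(m2$diameter_um / m1$diameter_um - 1), 0.02)
  expect_lt(abs(m2$thickness_um / m1$thickness_um - 1), 0.05)
})
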