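# ringprofiler

Quantification of ring-patterned fluorescent microcapillary networks from
calibrated grayscale microscopy images — for labs that pattern endothelial
cells into annular condensates (e.g. by acoustic patterning in hydrogel)
and want reproducible, scriptable readouts of how the resulting vascular
bed develops under co-culture or drug treatment.

## The method

The core statistic is the **radial intensity profile**: with the region of
interest placed concentrically with the pattern, pixel intensities are
aggregated as a function of radial distance *r* from the centre, swept
over 360°. For a ring-shaped network the profile shows a single
characteristic peak, and the biology is read off the curve:

* **diameter** `D = 2 · argmax_r P(r)` — twice the peak radius;
* **thickness** — the peak's full width at half maximum (FWHM), with a
  pedestal-robust baseline;
* **AUC** `∫ P(r) dr` — total signal, tracked longitudinally as a ratio to
  a baseline day;
* **continuity** — the sum-aggregated peak intensity, which for fixed
  geometry and amplitude is proportional to the lit arc fraction, plus an
  independent angular-occupancy index that measures the arc directly;
* **network area** — foreground area of a deterministic binary mask,
  reported per day as percent of the day −1 baseline;
* **group comparisons** — one-way ANOVA with Dunnett many-to-one tests
  against a control condition.

A synthetic image generator (annulus with Gaussian cross-section over
random-walk filaments, seeded noise, day-indexed dynamics) provides exact
ground truth, so the whole chain is validated by parameter recovery. See
the methods vignette (`vignettes/ring-quantification.Rmd`) for the model,
the design choices and their rationale.

## Worked example

Simulate one patterned well (3.58 mm field, 8 µm/px, ring 1781 µm /
416 µm with branched background and acquisition noise), measure it, then
track a programmed growth-and-regression timecourse:

```r
library(ringprofiler)

spec <- ring_spec(image_size_px = c(448, 448), microns_per_pixel = 8, seed = 7)
sim  <- generate_ring_image(spec, noise_spec(seed = 7))
measure_ring(sim$frame)
#> $ diameter_um      <dbl> 1785.331
#> $ thickness_um     <dbl> 413.2032
#> $ peak_intensity   <dbl> 19477.23
#> $ auc              <dbl> 8896724
#> $ continuity_index <dbl> 1
#> $ no_peak          <lgl> FALSE
```

The generator's truth is diameter 1781 µm and thickness 416 µm: recovery
is within 0.3 % and 0.7 % under default noise. A randomly organised
network measured the same way returns a `no_peak` record with absent
readouts instead of numbers.

```r
dyn <- dynamics_spec(days = c(-1L, 0L, 2L, 4L),
                     area_multiplier = c(1, 1.1, 1.45, 1.05))
tc <- generate_timecourse(spec, noise_spec(seed = 7), dyn)
relative_growth(tc$frames)
#>     day total_area_um2 relative_growth_percent
#> 1    -1        4394880                    100
#> 2     0        4895424                    111.
#> 3     2        6553536                    149.
#> 4     4        4735168                    108.
```

The programmed day-2 area (145 % of baseline) is recovered at 149 %.
Group effects are tested against the control with Dunnett's procedure:

```r
df <- data.frame(
  group = rep(c("control", "cisplatin", "combo"), each = 3),
  auc_ratio = c(1.00, 1.02, 0.98, 1.31, 1.27, 1.33, 1.30, 1.36, 1.29))
dunnett_test(df, auc_ratio, group, control = "control")
#> One-way ANOVA: F(2, 6) = 104.349, p = 2.183e-05
#>   comparison          estimate p_adjusted stars significant
#> 1 cisplatin - control    0.303  0.0000331 ****  TRUE
#> 2 combo - control        0.317  0.0000258 ****  TRUE
```

Each result type has an `autoplot()` method; fits have `tidy()` and
`glance()`. `run_experiment()` orchestrates the full
simulate/load → project → measure → track → compare workflow and writes
CSV/JSON reports plus a manifest of every resolved setting.

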