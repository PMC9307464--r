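---
title: "Quantifying ring-patterned microcapillary networks from fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ring-patterned microcapillary networks from fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Acoustic patterning can condense endothelial cells suspended in a hydrogel
into a ring a couple of millimetres across. The cells then self-assemble
into a microcapillary network that keeps the ring layout: a bright, thick
annular condensate surrounded by a dimmer, highly branched capillary bed.
Because the pattern is radially symmetric, its entire geometry can be read
out from one-dimensional statistics of a single fluorescence channel — no
segmentation of individual vessels is needed. That is what this package
implements:

* the **radial intensity profile** — aggregated pixel intensity as a
  function of radial distance from the pattern centre, swept over 360°;
* **ring readouts** derived from it — diameter (profile peak position),
  thickness (full width at half maximum), total signal (area under the
  curve), and ring continuity;
* **network-area tracking** — a binary mask of the fluorescent network,
  its total area, and day-by-day growth relative to a baseline day;
* **group statistics** — one-way ANOVA with Dunnett many-to-one
  comparisons against a control condition;
* a **synthetic image generator** with exact ground truth, so every stage
  can be validated quantitatively without microscope data.

```{r, eval = FALSE}
library(ringprofiler)
sim <- generate_ring_image(
  ring_spec(image_size_px = c(448, 448), microns_per_pixel = 8),
  noise_spec()
)
measure_ring(sim$frame)
```

## The radial profile

For a calibrated frame and a centre estimate, every pixel at distance
`d < r_max` from the centre contributes once to the radial bin
`floor(d / bin_width)`. Two aggregations are first-class:

* **mean** (default) — per-bin mean intensity. This is coverage-normalised:
  a full and a half ring of equal amplitude have the same *shape*, so mean
  profiles are the right basis for geometry (peak radius, FWHM) and for
  AUC comparisons across days.
* **sum** — per-bin total intensity. At the concentric centre all pixels of
  the annulus crest fall into a single bin, so the sum-profile peak totals
  the whole crest. That makes it proportional, for fixed geometry and
  amplitude, to the fraction of the circle that is present — the basis of
  the continuity readout below.

Bin width defaults to one pixel and radii are reported at bin centres.
Bins that extend past the image border simply collect fewer pixels, which
is visible in the `n_pixels` column; the implementation is validated
bit-for-bit against a naive double-loop accumulation, and pixel counts are
checked to conserve exactly.

## Centre placement

Real workflows place the region of interest concentrically by hand. For a
reproducible automatic rule the package offers:

* `intensity_centroid` (default) — exact for symmetric patterns, cheap,
  and adequate whenever the ring is close to complete;
* `refined` — needed for broken rings, where the centroid is biased toward
  the remaining arc (for a half ring the bias is about `2R/π`, several
  hundred micrometres). The refinement locates crest pixels (those above
  the profile's half-maximum level within the peak band, with sparsely
  occupied angular sectors dropped as gaps) and fits a circle to them by
  intensity-weighted Gauss–Newton least squares, iterating a few times
  from the centroid.

We initially tried refining the centre by maximising profile peak
sharpness (peak value / FWHM) over a local grid, and document here why
that was abandoned: for partial arcs the sharpness landscape has strong
false optima at circles that *osculate* the arc from inside (a fold
caustic concentrates a long stretch of crest into a narrow radial band),
and smoothing the objective flattens the true optimum instead. Measured on
half rings, sharpness-style objectives landed 20–110 px from the true
centre; the crest circle fit lands within about one pixel, noiseless and
noisy alike, because the crest genuinely lies on a circle around the true
centre for any arc fraction.

## Peak, thickness, AUC

The **peak** is the profile's global maximum; ties break toward the
smaller radius and are flagged, and an optional three-point parabolic
refinement (on by default, flagged in the output) gives sub-bin radius
precision. The ring diameter is twice the peak radius.

The **FWHM** uses the level `baseline + (peak − baseline)/2`, with
crossings located by linear interpolation between adjacent bins. The
baseline defaults to the median of the profile outside the peak ± 3 × an
initial half-width guess, which removes the pedestal contributed by the
branched background; a zero baseline is available and the choice is
recorded, because on pedestal-heavy images it shifts the thickness
readout. If the half level is never crossed on one side, the result is
flagged and reported as twice the available half-width rather than
silently truncated.

The **AUC** is the trapezoidal integral of the profile over radius.
Absolute AU depend on acquisition gain, so longitudinal comparisons are
reported as ratios against a baseline day (`compare_days()`), and
treatment effects as percent differences versus a control condition.

**Is there a ring at all?** Unpatterned networks must yield a `no_peak`
record, never fabricated readouts. The decision is made on a smoothed copy
of the profile (running mean over 75 µm): a true annulus is hundreds of
micrometres wide, whereas a stray filament crossing some circle
tangentially spikes only a few adjacent bins. The smoothed peak must
exceed the profile's lower quartile by five times that quartile; the
quartile, unlike the median, cannot be contaminated by a wide annulus
band. On generator images at the default conditions the two classes are
separated by an order of magnitude (prominence ≲ 3 for random networks,
≳ 15 for rings, threshold 5), and the discrimination test in the suite
verifies 20/20 seeds in each direction.

## Ring continuity, twice

The field's continuity readout is the **sum-profile peak intensity**: with
fixed geometry and amplitude it is exactly proportional to the lit arc
fraction (validated at 0.50 ± 2 % for a half ring). It has a documented
confounder — it scales equally with amplitude — so the package also
provides an independent **angular occupancy index**: the fraction of 1°
sectors of the annulus `radius ± thickness/2` whose mean intensity exceeds
a threshold. The default threshold is Otsu on the annulus pixels, capped
at half the annulus's 95th-percentile intensity; the cap guards the fully
continuous ring, where the histogram is unimodal and an uncapped Otsu
split would darken arbitrary sectors. Across an arc-fraction sweep the two
measures agree with R² > 0.9, which is what justifies using the cheap
proxy on real images.

## Masking and area tracking

The network mask drives the growth readout, reported as percent of the
baseline-day (day −1) area, the scale on which a day-2 value of 145 %
means 45 % growth (a delta convention is a switch). Thresholding is global
and deterministic. Plain two-class Otsu is provided but is *not* the
default: these images carry three intensity classes — background, dim
branched capillaries, and a bright condensed crest — and two-class Otsu
then splits between the two *signal* classes, discarding the entire
branched network (we measured thresholds landing ~60 % above the filament
amplitude). The default `half_peak` method instead partitions the
histogram with a three-class Otsu, reads the characteristic amplitude of
the dim signal class off as its histogram mode, and thresholds at half
that amplitude — the same half-maximum convention as every other footprint
in the package. A background-bulk guard and a two-class fallback cover
degenerate histograms. Objects below 100 µm² are removed as speckle; the
threshold actually used is always recorded on the mask.

## Group statistics

Treatment groups are compared to a control with one-way homoscedastic
ANOVA followed by Dunnett's many-to-one test; adjusted p-values come from
the joint multivariate-t distribution of the comparison statistics
(`multcomp`), with the quadrature seed fixed for reproducibility.
Significance stars follow the four-tier scale (`*` < 0.0332,
`**` < 0.0021, `***` < 0.0002, `****` < 0.0001) as presentation only,
decoupled from the testing alpha. A simulated null (three treatments,
n = 3, 1000 replicates) keeps the family-wise error at or below nominal,
and adjusted p-values are verified never to undercut unadjusted ones.
Replicate images can be pooled as observations or first averaged per
experiment; the mode used is recorded in the run manifest.

## The synthetic generator

The generator emulates the statistical structure of the emulated assay's
micrographs, with exact bookkeeping of the truth:

* **Field**: 3.58 mm × 3.58 mm, rendered by default at 4 µm/px (an 895 px
  field). The pixel size is configurable; the test suite and acceptance
  script render the same physical field at 8 µm/px (448 px), which keeps
  a full run in tens of seconds without changing any physical quantity by
  more than the stated tolerances (a resolution-stability test pins the
  truth area change at < 2 % between the two).
* **Ring**: an annulus with radially Gaussian cross-section — peak radius
  at half the nominal diameter (default 1781 µm), FWHM equal to the
  nominal thickness (default 416 µm) — times an angular indicator covering
  `arc_fraction` of the circle (a single contiguous seeded gap by
  default, the simplest monotonicity probe; explicit gap layouts are
  accepted). The Gaussian cross-section is a modelling choice, made so
  that the FWHM readout recovers the generating thickness by
  construction.
* **Branches**: smoothed random-walk filaments with Gaussian transverse
  profile (default 40 filaments, 600 µm long, 20 µm wide, reflecting at
  the field borders). Branching statistics are free parameters, not
  claims about real capillaries.
* **Replicate variability**: per-replicate diameters and thicknesses drawn
  from normal laws (defaults 1781 ± 142 µm and 416 ± 124 µm), truncated by
  rejection to geometries that fit the field.
* **Dynamics**: per-day maps for thickness, continuity, and target total
  area relative to day −1. The area target is met by deterministically
  extending or truncating the shared filament walks (bisection until the
  ideal-image area is within 1 % of target), so programmed growth such as
  a day-2 ×1.45 is true by construction and its recovery is a genuine
  end-to-end test.
* **Noise**: linear shading, Poisson shot noise, and Gaussian read noise,
  then clamping to the 16-bit range. The emulated study publishes no noise
  characterisation, so the defaults (read noise 300 AU, 0.01
  photons/AU, 10 % shading) are chosen as plausible fluorescence
  statistics and are explicitly *not* validated against real data.

**Ground truth** records centre, radius, thickness, arc fraction and
foreground area. The truth footprint is the ideal image above half the
amplitude of its dimmest structure — one global half-maximum rule. We
initially book-kept per-component half-max masks and dropped that
definition: when components differ in amplitude, no single global
threshold can reproduce per-component half-max footprints (the footprint
width of a Gaussian structure scales as √ln(A/t), which cannot match two
amplitudes at once), so truth and any realistic measurement would disagree
for reasons that have nothing to do with measurement quality.

**What passing tests do not show.** The generator reproduces the *shape
statistics* the pipeline consumes, not real micrographs: there is no
capillary texture or anastomosis, no three-dimensional blur or
depth-dependent attenuation, no photobleaching, no uneven gel
autofluorescence beyond a linear ramp, and the annular cross-section is
exactly Gaussian. Recovery results on synthetic data therefore validate
the measurement chain's correctness and its noise robustness at the
stated noise levels — they do not certify performance on arbitrary real
images, where centre placement and baseline choices should be reviewed
via the recorded flags and provenance.

## Numerical choices and degenerate inputs

* Radial bin width ≥ one pixel; bins at centres; `r_max` defaults to the
  nearest image border from the centre.
* Peak ties break toward smaller radius; parabolic refinement is skipped
  at ties, at profile ends, and when the curvature is non-negative —
  always flagged rather than silent.
* All-zero profiles yield `no_peak` records, distinct from errors;
  all-zero frames refuse centre estimation with an explicit error.
* Constant images refuse thresholding, naming the degenerate histogram.
* Geometry that cannot fit (ring exceeding the field, annulus outside the
  image, unreachable area multipliers) raises typed errors rather than
  clipping silently.
* Identical specs and seeds reproduce every image bit-for-bit; per-day and
  per-replicate seeds are derived additively from the user seed.

## Problem sizes used in the validation suite

Unit and acceptance tests run the full 3.58 mm field at 8 µm/px (448 px)
or, for sampling-heavy checks, 28 µm/px (128 px); growth tracking uses 10
seeded timecourses of three days; discrimination uses 20 seeds per class;
the Dunnett null uses 1000 replicates of a 4 × 3 design. These sizes were
chosen so the complete suite runs in a couple of minutes on one CPU while
every tolerance stated above is still binding.

## Limitations

* Area is the only mask-level readout: no skeletonisation, branch counts
  or junction metrics.
* Tile stitching, flat-field correction, registration and deconvolution
  are out of scope; inputs are assumed stitched and single-channel.
* The continuity proxy confounds amplitude with continuity; use the
  angular index when acquisition gain varies between days.
* Physical readouts are only as good as the supplied calibration
  (µm/px, z-step); image metadata is deliberately not trusted.
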