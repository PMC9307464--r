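Package: ringprofiler
Title: Radial-Profile Quantification of Ring-Patterned Microcapillary Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ring-shaped fluorescent microcapillary networks from
    calibrated grayscale microscopy images. Implements the radial intensity
    profile statistic (integrated intensity versus radial distance from the
    pattern centre, swept over 360 degrees) and the readouts derived from it:
    ring diameter from the profile peak, thickness from the full width at half
    maximum, area under the curve, and ring continuity via both the peak
    intensity proxy and a direct angular occupancy index. Also tracks total
    network area over day-indexed timecourses relative to a baseline day, and
    compares treatment groups against a control with one-way ANOVA followed by
    Dunnett's many-to-one test. Ships a synthetic fluorescence image generator
    with exact ground truth so every stage of the pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    multcomp,
    pracma
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
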