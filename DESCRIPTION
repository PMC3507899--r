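Package: mousegait
Title: Quantitative Gait Analysis for Illuminated-Footprint Walkway Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of CatWalk-style quantitative gait data for
    mouse models of Parkinson's disease. Provides a calibrated synthetic-data
    generator for illuminated-footprint runway crossings (paw-contact events,
    luminance frame stacks, open-field trajectories and per-animal tyrosine
    hydroxylase levels coupled through a latent lesion-severity variable),
    paw-print detection and tracking from frame stacks, the full battery of
    temporal, spatial and interlimb-coordination gait parameters (stance, swing,
    step cycle, duty cycle, stride length, swing speed, cadence, walking-speed
    variation, base of support, dual stances, support-phase fractions, step
    patterns and regularity index), open-field path-length readouts, and
    group-comparison and correlation reporting (one-way ANOVA, Pearson
    correlations of gait readouts against neurochemical markers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    EBImage,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
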