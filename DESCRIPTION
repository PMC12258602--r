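Package: spinalign
Title: Spine-to-Back-Shape Registration Geometry and Rater Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the relationship between internal spinal
    alignment and external back shape in scoliosis. Provides a synthetic
    cohort generator (parametric scoliotic spine centerlines, biplanar
    parallel projections, back-surface outlines, and noisy rater
    annotations), SVD-based rigid point-set registration and marker
    reconstruction, Cobb-angle extraction from smoothing-spline
    centerlines, posture-alignment error between lateral outlines,
    Procrustes (rotation and translation only) correlation between the
    spinous-process line and the internal spinal line, and the reliability
    statistics used in inter-/intrarater studies: linear mixed-effects
    models, intraclass correlation coefficients with bootstrap confidence
    intervals, equivalence testing on confidence intervals, and
    equivalence-power simulation over effect-size grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
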