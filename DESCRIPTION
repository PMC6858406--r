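Package: musclevol
Title: Estimating Lower-Limb Muscle Group Volumes from Ultrasound and
    Anthropometric Measurements
Version: 0.1.0
Authors@R:
    person("musclevol", "developers", email = "musclevol@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the volume of the hip extensor, knee
    extensor, knee flexor, and ankle plantarflexor muscle groups from
    B-mode ultrasound and anthropometric measurements. Provides criterion
    volume computation by trapezoidal integration of serial axial
    cross-sectional areas, between-session reliability as the typical
    error of measurement, a regression model-development pipeline with a
    seven-criterion diagnostic battery and holdout cross-validation, the
    four published clinical prediction equations with sensitivity checks,
    and a synthetic cohort generator that reproduces the statistical
    structure the analysis assumes so that every stage can be exercised
    without access to the original study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
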