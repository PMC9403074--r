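Package: aortaZ
Title: Z-Score Reference Charts for Fetal Ascending Aorta Diameter and
    Distensibility
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Construction and application of gestational-age-conditional
    reference charts for fetal ascending aorta diameters (maximum systolic
    Dmax, minimum diastolic Dmin, both in mm) and diameter distensibility
    ((Dmax - Dmin)/Dmin), measured at the sinotubular junction.  Implements
    the classical three-step Z-score chart construction for heteroscedastic
    biometry: a polynomial regression of the mean on gestational age (or
    biparietal diameter or femur length), a second regression of the
    standard deviation on the same predictor, and standardisation of
    observations as (observed - predicted mean)/predicted SD.  Ships a
    registry of published reference equations, percentile-curve evaluation,
    normality and band-coverage diagnostics (P-P plots, Shapiro-Wilk,
    coverage, balance), intraclass correlation coefficients for
    repeatability studies, and a seeded synthetic-cohort generator for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
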