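Package: vpdgrowth
Title: Tree Growth Responses to Atmospheric Vapour Pressure Deficit
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking boreal tree radial growth to atmospheric
    dryness. Derives daily vapour pressure deficit (VPD) and a soil moisture
    index from daily weather, converts ring-width series to basal area
    increments, fits site-by-species penalized-spline mixed models with AR1
    residuals and tree random intercepts, classifies VPD sensitivity from
    coefficient t-values, attributes sensitivity to site predictors with a
    bagged regression forest (permutation importance, minimal depth, partial
    dependence), and computes autocorrelation-corrected growth-change and
    trend statistics. Includes a synthetic data generator with known ground
    truth and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
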