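Package: cropbins
Title: Temperature-Bin Exposure Regression for Crop Yield Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the response of county crop yields to the time the
    growing season spends in discrete temperature intervals. Computes
    within-day exposure times from daily minimum and maximum temperature by
    sinusoidal interpolation, aggregates grid-cell exposures to counties with
    land-use weights, fits a fixed-effects panel regression of log yield on
    binned exposure with precipitation and state-trend controls, and computes
    spatial-HAC (Conley-type) standard errors with a distance cutoff. Includes
    seeded generators for gridded daily weather, county maps and yield panels
    (from the regression model itself or from a soil-water-bucket surrogate
    crop model), confidence-interval-overlap divergence counting for comparing
    observed and simulated response curves, and a decomposition of warming
    impacts into per-temperature-range multiplicative yield change factors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
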