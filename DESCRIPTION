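Package: heatmort
Title: Generalized Temperature-Mortality Exposure-Response Functions and
    Heat-Attributable Death Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-city quadratic temperature-mortality exposure-response
    functions, generalizes them across locations by regressing their
    coefficients on summer mean temperature (SMT), and projects
    heat-attributable premature deaths on gridded daily temperature fields
    under climate scenarios with explicit adaptation representations
    (adaptation to SMT, lagged adaptation to the optimal temperature) and
    quadrature propagation of fractional uncertainties. Includes a
    synthetic-data module that emulates the statistical structure of gridded
    daily temperatures (seasonal cycle, AR(1) noise, warming trend),
    gridded population, monthly mortality weighting, and city
    exposure-response curves with known ground truth, so the whole pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
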