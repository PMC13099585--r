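Package: foremort
Title: Mortality Effects of Temperature Forecast Errors: Estimation and
    Scenario Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate how daily temperature and day-ahead
    temperature forecast errors jointly affect county-month mortality, and
    to project lives saved under combinations of climate-warming and
    forecast-accuracy scenarios.  Provides a synthetic county-panel
    generator with a known response surface for parameter-recovery
    studies; a 13-column polynomial-by-natural-spline design basis;
    weighted fixed-effects panel estimation with cluster-robust inference;
    conditional forecast-error mean and variance models with binned
    standardized-error resampling; expert-elicitation aggregation via
    skew-lognormal mixtures; and excess-mortality projection relative to
    the minimum mortality temperature.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    splines,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
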