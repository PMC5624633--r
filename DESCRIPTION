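Package: recatch
Title: Catch and Effort Data Reconstruction and CPUE Standardization for
    Longline Fisheries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs catch and effort series for longline fisheries
    with incomplete logbook coverage and derives a standardized abundance
    index. Provides Monte Carlo estimation of fish numbers from landing
    weights via a weight-per-fish distribution, classification of
    vessel-days into fishing and non-fishing days from hourly track data
    (speed, within-day distance, and direction-change criteria scored by
    sensitivity and specificity), zero-intercept regressions linking
    fishing days to at-sea days by port and vessel class, delta-lognormal
    mixed-model CPUE standardization with AIC/BIC stepwise selection and
    bias-corrected least-squares-means indices, and cross-validated
    overall R-squared comparison of area-separated versus area-combined
    standardizations. A seeded synthetic-data generator emulates the
    landings, tracks, trips and trip-level CPUE tables of a bluefin tuna
    longline fleet so the full pipeline is testable without confidential
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    emmeans,
    geosphere,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
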