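Package: rivet
Title: Indirect Reference Interval Estimation and Verification for
    Clinical Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the central-95% reference interval of a laboratory
    analyte from mixed routine data containing an unknown proportion of
    pathological results. The estimator selects a Gaussian or lognormal
    working model from Bowley's quartile skewness, strips pathological
    tails by iterative boxplot-based truncation, and extrapolates the
    2.5th and 97.5th percentiles from a regression in a truncated normal
    quantile-quantile plot. Estimated limits are compared with target
    limits through tolerance zones derived from the permissible
    uncertainty of quantitative laboratory results, yielding traffic-light
    verdicts (green/yellow/red) for rapid serial verification. Includes
    closed-form 95% confidence intervals calibrated by Monte Carlo
    simulation, seeded simulators for method evaluation, and a
    command-line interface for batch verification from CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
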