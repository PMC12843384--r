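Package: complexitrend
Title: Log-Linear Growth of Biological Complexity Features and
    Origin-Time Extrapolation
Version: 0.1.0
Authors@R: person("complexitrend", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for analysing the growth of biological complexity
    features (genome length, gene number, protein-protein binding sites,
    cell volume, energy budgets, molecular complexity indices) as
    log-linear trends over evolutionary time. Provides ordinary and
    weighted least-squares fits of log-feature versus origin time,
    back-extrapolation to minimal-complexity anchor features, the
    slope-ratio decomposition of log-log (allometry-style) exponents, a
    time-ruler calibration for log-log plots, Monte Carlo propagation of
    bivariate (feature and time) uncertainty, a synthetic-data generator
    with the statistical structure the analyses assume, and alignment of
    extrapolated origin eras with the cosmic star-formation history under
    flat Lambda-CDM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
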