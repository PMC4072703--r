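Package: fawnsurv
Title: Neonatal Ungulate Survival, Resource Selection and Multi-Predator
    Risk Surfaces
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing neonatal ungulate
    (white-tailed deer fawn) survival from radio-telemetry: synthetic
    landscape and telemetry generation, use-availability resource
    selection functions with crossed random intercepts, composite
    multi-predator risk, maternal-effect covariates (winter severity
    index, birth-mass back-calculation), a ranked set of Cox
    proportional-hazards models with Gaussian frailties, and spatial
    extrapolation of suitability, risk and mortality surfaces onto a
    square-cell landscape grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
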