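Package: usualintake
Title: Usual Dietary Intake Distributions from Repeated 24-Hour Recalls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates population distributions of usual ("nearly-daily")
    nutrient intake from repeated 24-hour dietary recalls, correcting for
    within-person day-to-day variation. Fits a Box-Cox transformed linear
    mixed model with between- and within-person variance components,
    simulates a pseudo-population of usual intakes by multiple imputation of
    between-person deviations with Gauss-Hermite back-transformation, and
    summarises means, percentiles and prevalences of inadequate or excessive
    intake by the EAR cut-point and full-probability methods. Supports
    single-recall surveys via an external within:between variance ratio,
    scenario modelling of fortification (add-then-shrink) and supplement or
    breast-milk contributions (shrink-then-add), and standard errors by
    Balanced Repeated Replication with Fay adjustment or bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    yaml,
    optparse
Config/testthat/edition: 3
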