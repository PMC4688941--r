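Package: smokedyn
Title: Social Dynamics of Smoking Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a century of smoking prevalence as a binary-choice social
    dynamic: adoption and cessation rates balance individual utility, which
    decays as published knowledge of health effects accumulates, against
    social (conformity) utility weighted by a country-specific conformity
    exponent. Provides the rate law and trajectory simulation, estimation of
    historical prevalence from cigarette-consumption records via per-country
    affine maps with quality filtering and Grubbs outlier screening, an
    alternating local/universal bounded least-squares calibration, trend and
    cross-country correlation statistics against an individualism index, a
    counterfactual cumulative-consumption calculation, and a fully seeded
    synthetic-data generator for offline pipeline testing and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
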