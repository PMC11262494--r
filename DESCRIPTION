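Package: brmcda
Title: Quantitative Benefit-Risk Assessment with Utility-Weighted MCDA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative benefit-risk evaluation of two-arm clinical
    trials: exposure-adjusted incidence-rate differences per 10 000
    patient-years with Wald confidence intervals, number needed to
    treat/harm, Kaplan-Meier cumulative-incidence difference curves with
    an at-risk restriction, and a multi-criteria decision analysis
    (MCDA) in which endpoint rate differences are weighted by health
    state utility values so that the benefit-risk balance is expressed
    in utility death equivalents per 10 000 patient-years. Monte Carlo
    simulation propagates rate and weight uncertainty into the score
    distribution and the probability that benefits outweigh risks,
    with one-way weight sensitivity (tornado) and a temporal
    benefit-risk trajectory on a Kaplan-Meier grid. Includes a
    calibrated synthetic two-arm trial generator, an
    intention-to-treat versus on-treatment scoping layer, and the
    published aggregate inputs of a peripheral-artery-disease
    anticoagulation trial as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    parallel,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
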