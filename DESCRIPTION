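Package: aldoCEA
Title: Cost-Effectiveness Modelling of Primary Aldosteronism Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort modelling of comprehensive
    work-up strategies for primary aldosteronism (screening, CT, adrenal
    venous sampling, adrenalectomy and radiofrequency ablation) against
    medication-only management of hypertension, from a healthcare-payer
    perspective with costs in Japanese yen. Provides the full published
    parameter set as a validated fixture, strategy resolution into weighted
    sub-cohorts, a four-state annual-cycle cohort engine (hypertension,
    heart failure, stroke, death) with discounting and half-cycle
    correction, incremental cost-effectiveness ratios with dominance
    classification, one-way deterministic sensitivity analysis with tornado
    ranking, a life-expectancy threshold sweep, Monte-Carlo probabilistic
    sensitivity analysis with method-of-moments beta/gamma distributions,
    and an independent individual-level microsimulation oracle for
    validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
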