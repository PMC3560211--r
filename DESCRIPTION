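Package: cvdprevent
Title: Cost-Effectiveness Modelling of Cardiovascular Disease Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model for evaluating the
    cost-effectiveness of primary prevention of ischaemic heart disease and
    stroke with blood pressure-lowering and statin drugs. Implements
    five-year absolute cardiovascular risk scoring (Anderson 1991 Framingham
    equation) with treated-level adjustment and population calibration,
    guideline-based and absolute-risk screening eligibility, multiplicative
    drug treatment effects with first-year discontinuation, government and
    patient cost accounting, lifetime QALY estimation with 3% discounting,
    incremental cost-effectiveness ratios, and multivariate probabilistic
    sensitivity analysis. Ships a synthetic population generator emulating a
    national risk-factor survey so the full analysis is reproducible without
    restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
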