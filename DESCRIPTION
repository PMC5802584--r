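Package: petcovnet
Title: Equilibrium DVR Quantification and Receptor Covariance Network
    Comparison for PET Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for regional PET neuroreceptor binding
    studies that compare two groups: distribution volume ratio (DVR)
    quantification from bolus/infusion time-activity curves using a late
    equilibrium window and a reference region; per-region Welch and
    covariate-adjusted general linear model comparisons with partial
    eta-squared effect sizes; a three-step inter-regional correlation
    (receptor covariance network) comparison based on Fisher's r-to-z
    transformation with per-pair one-tailed tests and a global Welch test
    over all unique region pairs; simulation-based type-I-error
    calibration of that procedure; clinical scoring and brain-behaviour
    association utilities; and a calibrated synthetic two-group cohort
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
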