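Package: betaconn
Title: Beta-Series Functional Connectivity for Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-wise beta-series functional connectivity analysis for
    event-related task fMRI, built around a social-interactive 2x2 child
    paradigm. Provides least-squares-single (LSS) trial-wise GLM estimation
    with duration-modulated hemodynamic regressors, framewise-displacement
    motion quality control with run- and subject-level exclusion rules,
    ROI-network connectivity summaries (within- and between-network means,
    node strengths), and a linear mixed-effects inference suite with
    post-hoc contrasts and false-discovery-rate correction. A synthetic
    cohort generator plants known connectivity structure, age effects and
    behavioral effects so that every pipeline stage can be validated
    against a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    car,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
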