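Package: ewscompare
Title: Early Warning Score Comparison with Paired AUROC Analysis
Version: 0.1.0
Authors@R:
    person("Emergency", "Scores", email = "ews@example.org", role = c("aut", "cre"))
Description: Tools for comparing aggregate early warning scores (EWS) in
    emergency-department cohorts. Ships data-driven scoring engines for the
    Central Denmark Region score TOKS, an oxygen-augmented variant (mTOKS),
    and the 2012 Royal College of Physicians National Early Warning Score
    (NEWS); a cohort-construction pipeline with eligibility filters,
    first-contact deduplication, first-complete-vital-set selection and a
    7-day mortality outcome; nonparametric ROC/AUROC estimation with DeLong
    variance components and the paired chi-square test for correlated AUROCs;
    a synthetic emergency-cohort generator for fully offline validation; and
    command-line entry points producing patient-flow, cohort-characteristics
    and discrimination reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
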