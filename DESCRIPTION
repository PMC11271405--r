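Package: pgtkit
Title: Outcome Analysis for Precision-Guided Treatment Trials
Version: 0.1.0
Authors@R: person("PGT", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end outcome-analysis machinery for precision-oncology
    cohort studies in which a molecular tumor board issues tiered treatment
    recommendations. Adjudicates treatment responses under four
    modality-specific rule sets (RECIST-style, RANO-style, PERCIST-style and
    blast-count criteria for acute leukemia), derives per-course clinical
    endpoints (best response, objective clinical benefit, progression-free
    survival, intra-patient PFS ratio, favorable-factor score), assigns
    overall-survival comparison groups, and provides a self-contained
    statistical kernel (Kaplan-Meier estimation, log-rank test, Cox
    proportional-hazards regression with Efron or Breslow ties, chi-squared
    proportion tests and exact binomial confidence intervals). A synthetic
    cohort generator with configurable hazard structure makes every pipeline
    stage testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
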