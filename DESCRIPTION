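Package: faersvte
Title: Disproportionality and Time-to-Onset Analysis of Drug-Associated
    Venous Thromboembolism in Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analysis of venous
    thromboembolism (VTE) in FAERS-style quarterly adverse-event tables:
    case deduplication by the FDA rule (latest FDA_DT, highest PRIMARYID
    per CASEID), MedDRA preferred-term cohort construction restricted to
    primary-suspect drug mentions with synonym-to-ingredient mapping,
    four disproportionality algorithms (ROR, PRR with Yates chi-square,
    BCPNN information component, MGPS empirical-Bayes gamma-Poisson
    shrinkage) with a combined four-criteria signal rule and A/B/C/D
    ROR-percentile risk stratification, Weibull time-to-onset modelling
    with failure-mode classification, cumulative-incidence and log-rank
    group comparison, and descriptive reporting. Ships a seeded synthetic
    FAERS generator with full ground truth so every stage is testable
    without any download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
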