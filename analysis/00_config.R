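# Shared study configuration for the analysis scripts.
#
# The simulated spontaneous-report database: 50 000 cases over a panel of
# 30 drugs spanning the ATC classes most represented among
# thromboembolism signals, 5 of which carry injected associations of
# graded strength (reporting ratios 10 down to 4), a 5% duplicate-report
# fraction, and 10% of dates degraded to partial precision. One seed
# drives everything; rerunning any script reproduces its outputs exactly.

library(faersvte)

results_dir <- file.path("results")
data_dir <- file.path("scratch", "data") # bulky raw tables, regenerable

study_config <- function(seed = 20240901L) {
  drugs <- synthetic_drug_panel(
    n_drugs = 30L, n_assoc = 5L, rr = 10, use_prob = 1 / 30,
    tto_alpha = c(120, 30, 365, 60, 10, 200),
    tto_beta = c(0.65, 1.0, 1.5, 0.8, 2.0, 0.7)
  )
  drugs$rr[1:5] <- c(10, 8, 6, 5, 4)
  synthetic_config(
    n_cases = 50000L,
    duplicate_fraction = 0.05,
    drugs = drugs,
    p_event_base = 0.01,
    degrade_frac = 0.10,
    seed = seed
  )
}

# rebuilds the deduplicated analysis dataset from the written quarter
# (scripts 02+ start from the files, exercising the ingest path)
load_dataset <- function(cfg = study_config()) {
  paths <- list(
    demo = file.path(data_dir, "DEMO24Q1.txt"),
    drug = file.path(data_dir, "DRUG24Q1.txt"),
    reac = file.path(data_dir, "REAC24Q1.txt"),
    ther = file.path(data_dir, "THER24Q1.txt"),
    outc = file.path(data_dir, "OUTC24Q1.txt"),
    rpsr = file.path(data_dir, "RPSR24Q1.txt")
  )
  if (!all(file.exists(unlist(paths)))) {
    stop("run analysis/01_simulate.R first to write the synthetic quarter")
  }
  raw <- read_quarter(paths)
  build_analysis_dataset(raw, cfg$target_pts, synthetic_dictionary(cfg))
}
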