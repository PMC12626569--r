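# faersvte

Pharmacovigilance analysis of drug-associated venous thromboembolism
(VTE) in FAERS-style spontaneous adverse-event reports, as a tested,
reusable R pipeline.

Spontaneous-report databases like the FDA Adverse Event Reporting System
(FAERS) are the main post-marketing instrument for spotting drugs whose
VTE reporting is disproportionately high. This package implements the
full analysis chain for such a study, for pharmacoepidemiologists and
drug-safety analysts:

* **Ingest & deduplication** — read the quarterly `$`-delimited ASCII
  tables (DEMO, DRUG, REAC, THER, OUTC, RPSR); per `CASEID` keep the
  report version with the latest `FDA_DT`, ties broken by the highest
  `PRIMARYID` (the FDA-recommended rule).
* **Cohort construction** — event-positive cases via a MedDRA
  preferred-term (PT) list; only primary-suspect (PS) drug mentions;
  verbatim names mapped to canonical ingredients with ATC codes through
  a synonym dictionary.
* **Disproportionality analysis** — per drug, the 2×2 table
  (a, b, c, d; N = a+b+c+d) against the database background, and four
  estimators:
  - ROR = ad/bc with Wald 95% CI;
  - PRR = [a/(a+b)]/[c/(c+d)] with the Yates-corrected χ²;
  - BCPNN information component IC = log2(aN/((a+b)(a+c))) with its
    lower credibility bound IC025;
  - MGPS empirical-Bayes geometric mean EBGM with its 5th percentile
    EBGM05 (closed form, or the full gamma-Poisson mixture fitted by
    marginal-likelihood maximization).

  A drug is a positive signal only when all four criteria hold at once
  (a ≥ 3 & ROR CI low > 1; a ≥ 3 & PRR ≥ 2 & χ² ≥ 4; IC025 > 0;
  EBGM05 > 2), and positives are stratified into risk levels A/B/C/D at
  the top 5% / 6–20% / 21–50% / 51–100% of ROR ranks.
* **Time-to-onset** — onset = (EVENT_DT − START_DT) + 0.5 days with
  principled exclusions; two-parameter Weibull fits (scale α in days,
  shape β) classifying each drug's onset hazard as early (β < 1),
  random (CI spans 1) or wear-out (β > 1) failure;
  cumulative-incidence curves and log-rank comparison across ATC
  classes.
* **Descriptives** — Table-1-style demographic/outcome summary and the
  annual trend of reports and death reports.
* **Synthetic FAERS generator** — seeded, fully deterministic quarterly
  tables with complete ground truth (injected associations, duplicate
  versions, Weibull onset models, demographic mixes), so every stage is
  testable without any download.

## Worked example

```r
library(faersvte)

cfg <- synthetic_config(
  n_cases = 20000,
  drugs   = synthetic_drug_panel(n_drugs = 10, n_assoc = 2, rr = 8),
  seed    = 42
)
gen <- generate_faers(cfg)
ds  <- build_analysis_dataset(gen$tables, cfg$target_pts, synthetic_dictionary(cfg))
ds
#> <analysis_dataset>
#>   reports (deduplicated): 20000
#>   event-positive reports: 531
#>   PS drug mentions: 20000 (10 ingredients)

sig <- compute_signals(ds)
dplyr::select(sig, drug, a, ror, ror_ci_low, ic025, ebgm05, combined_positive)[1:4, ]
#>   drug        a   ror ror_ci_low ic025 ebgm05 combined_positive
#> 1 drug002   181 4.82       4.00   1.47  2.82  TRUE
#> 2 drug001   170 4.53       3.75   1.42  2.73  TRUE
#> 3 drug010    30 0.543      0.374 -1.33  0.421 FALSE
#> 4 drug009    27 0.470      0.318 -1.55  0.363 FALSE

tto <- extract_tto(ds)
tto_summary(tto, by = NULL)[, c("n", "median", "q1", "q3", "alpha", "beta", "failure_mode")]
#>       n median    q1    q3 alpha  beta failure_mode
#> 1   430     32  11.5  93.5  67.1 0.693 early
```

The two drugs generated with an injected reporting ratio of 8 are the
two combined positives: ~180 co-reports each, ROR near 5 (the odds
ratio sits below the injected RR because the second injected drug
contaminates the comparator background), IC025 > 0 and EBGM05 > 2. The
null drugs sit near or below 1 on every scale. The onset summary pools
430 day-precision onset records (the rest are excluded as partial
dates): median 32 days, Weibull shape 0.693 with its CI below 1 —
early-failure onset, risk concentrated shortly after initiation.

## Analysis scripts

`analysis/01_simulate.R` … `06_descriptives.R` run the same pipeline as
a narrative workflow on a 50 000-case simulated cohort with graded
association strengths, writing each stage's tables under `results/`
(the raw simulated quarter goes under `scratch/`). Run them in order
from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_ingest_dedup.R
# ...
```

`run_pipeline(config, out_dir)` does the same end-to-end from a single
(YAML or list) configuration, writing a run manifest with seed and
config hash for provenance.

## Vignette

`vignettes/faers-vte-pipeline.Rmd` documents the statistical model, the
algorithm variants and their defaults, the numerical conventions
(continuity corrections, profile-likelihood Weibull fit, multi-start
mixture optimization), what the synthetic generator does and does not
emulate, and known limitations.
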