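---
title: "Disproportionality and time-to-onset analysis of drug-associated venous thromboembolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality and time-to-onset analysis of drug-associated venous thromboembolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(faersvte)
```

## The problem

Venous thromboembolism (VTE) — deep vein thrombosis and pulmonary
embolism — is a major preventable cause of hospitalization and death, and
a number of medications (hemostatic agents, hormonal contraceptives,
antineoplastics) are acquired risk factors. Spontaneous adverse-event
reporting databases such as FAERS are the main post-marketing instrument
for finding drugs whose VTE reporting is disproportionately high.
`faersvte` implements the complete analysis chain for such a study on
FAERS-style quarterly tables: case deduplication, cohort construction at
the MedDRA preferred-term (PT) level, four disproportionality algorithms
combined into one signal rule, percentile-based risk stratification of
the positive drugs, and Weibull time-to-onset modelling.

Because the real database is a multi-gigabyte download and the exact PT
list and drug-synonym dictionary of any given study are licensed or
unpublished, the package also ships a seeded synthetic generator that
emits structurally faithful quarterly tables with complete ground truth.
Every stage of the pipeline is tested against that ground truth.

## Data model and deduplication

A FAERS quarter is a set of `$`-delimited ASCII tables (DEMO, DRUG, REAC,
THER, OUTC, RPSR) keyed by `PRIMARYID` (one report version) and `CASEID`
(one safety case). Input is decoded as Latin-1, since the public files
contain non-UTF-8 bytes; rows whose field count disagrees with the header
are skipped and counted, never silently dropped.

Dates come at day, month or year precision, or broken. `parse_date()`
keeps the components plus a precision tag instead of coercing to `Date`,
because different stages need different precision: time-to-onset requires
day precision in both dates, while the annual trend only needs a year.

The same case is typically present in several versions. Following the
FDA-recommended rule, `deduplicate()` keeps, per `CASEID`, the row with
the latest `FDA_DT`, ties broken by the highest `PRIMARYID` (compared
numerically when the ids are all-digits). Partial receipt dates order by
(year, month, day) with absent components as zero; a case whose versions
all have unparseable receipt dates keeps the highest id and is logged.
Reports in the other tables belonging to non-surviving versions are
discarded. Deduplication runs on the pooled multi-quarter DEMO table
before any event filtering, mirroring how the full database is
deduplicated before cohorts are drawn, and it is idempotent.

## Cohort construction

A case is **event-positive** when at least one of its reaction PTs is on
the configured PT list — matched by MedDRA code when the table carries
one, by case-folded, whitespace-collapsed name otherwise. Codes are
preferred because they survive spelling and translation variation. The
bundled `vte_pt_list.csv` covers the common VTE PTs and is a clearly
marked editable stand-in, not the licensed MedDRA dictionary.

Only drug mentions with role code `PS` (primary suspect) enter the
signal analysis. Verbatim names are mapped to canonical ingredients
through a many-to-one synonym dictionary after normalization (case
folding, whitespace collapse, stripping of trailing dose/form tokens such
as `10MG` or `TABLET`). Fixed-dose combinations are their own
ingredients. Names that miss the dictionary are kept under their
normalized verbatim string and flagged: they still count toward the
report total `N`, but are excluded from per-drug ranking unless
explicitly enabled, so an unmapped synonym can never silently split a
drug's counts. Multiple PS rows of the same ingredient in one case
collapse to a single (case, ingredient) mention — the counting unit
everywhere is the deduplicated case.

## Disproportionality analysis

For each drug \(D\) the deduplicated cases are cross-classified against
the event \(E\):

|              | event          | no event |
|--------------|----------------|----------|
| drug (PS)    | \(a\)          | \(b\)    |
| other drugs  | \(c\)          | \(d\)    |

with \(N = a+b+c+d\). Four estimators are computed per table:

* **ROR** \(= ad/bc\) with Wald 95% CI
  \(\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})\).
* **PRR** \(= \frac{a/(a+b)}{c/(c+d)}\) with the Yates-corrected 2×2
  chi-square.
* **BCPNN information component**
  \(\mathrm{IC} = \log_2 \frac{aN}{(a+b)(a+c)}\), a shrunk
  observed-to-expected ratio in log2 units, with
  \(\mathrm{IC025} = \mathrm{IC} - 2\sqrt{V}\).
* **MGPS** \(\mathrm{EBGM}\), the empirical-Bayes geometric mean of the
  posterior relative reporting rate under a gamma-Poisson model, with its
  5th percentile \(\mathrm{EBGM05}\).

A drug is a **positive signal** only when all four criteria hold
simultaneously — the canonical thresholds in studies of this design,
configurable via `signal_thresholds()`:

\(a \ge 3\) and ROR CI lower bound \(> 1\); \(a \ge 3\), PRR \(\ge 2\)
and \(\chi^2 \ge 4\); IC025 \(> 0\); EBGM05 \(> 2\).

```{r}
ror(5, 95, 100, 9800)
prr_chi2(5, 95, 100, 9800)
bcpnn_ic(5, 95, 100, 9800)
mgps_ebgm(5, 95, 100, 9800)
```

### Variants

The exact Bayesian machinery behind published IC and EBGM values varies
between studies and is often not stated precisely, so both a full-Bayes
and a closed-form variant are provided for each, with the closed forms as
defaults for reproducibility:

* `bcpnn_ic(variant = "simplified")` (default) uses the raw observed
  component as the point IC and the three-term posterior variance of the
  beta/Dirichlet model for IC025; `variant = "bate"` uses the full
  posterior expectation and variance with the joint prior total chosen so
  that the expected IC is zero at independence. The two agree closely
  except at very small \(a\), where the full posterior shrinks the point
  estimate toward zero.
* `mgps_ebgm(variant = "closed_form")` (default) is the
  observed-to-expected ratio \(aN/((a+b)(a+c))\) with a log-normal lower
  bound; `variant = "em"` fits the two-component gamma mixture prior
  \((\alpha_1,\beta_1,\alpha_2,\beta_2,P)\) by maximizing the
  negative-binomial marginal likelihood over all supplied pairs and
  reports the exact posterior geometric mean and 5th percentile. The
  marginal likelihood is multi-modal, so the optimizer runs from three
  fixed starting points and keeps the best — deterministic, no random
  restarts. Non-convergence is an error carrying the last parameters.

### Numerical conventions

* **Zero cells.** When any cell is zero, the Haldane continuity
  correction (+0.5 to all four cells) is applied to ROR and closed-form
  EBGM and the result is flagged; a zero drug or comparator margin for
  the PRR is an error naming the margin.
* **Yates correction.** The chi-square uses the continuity-corrected
  statistic with the correction capped at \(|O-E|\) (as in
  `stats::chisq.test`), so exact independence gives exactly 0 rather
  than a spurious positive value; an uncorrected Pearson statistic is
  available with `yates = FALSE`.

### Risk stratification

Positive drugs are ranked by ROR descending — ties broken by larger
\(a\), then drug id, so the ordering is total and reproducible — and cut
at the top 5%, 6–20%, 21–50% and 51–100% of ranks into levels A–D.
Boundaries are floors of the cumulative rank: with \(n\) drugs, A ends at
\(\lfloor 0.05n \rfloor\), B at \(\lfloor 0.20n \rfloor\), C at
\(\lfloor 0.50n \rfloor\). With 135 positives this yields level sizes
6/21/40/68:

```{r}
drugs <- tibble::tibble(
  drug = sprintf("d%03d", 1:135),
  ror = seq(90, 1.5, length.out = 135), a = 25L
)
table(stratify_risk(drugs)$risk_level)
```

## Time-to-onset analysis

Onset time is the whole-day interval from therapy start (`START_DT`,
earliest day-precision start among the suspect drug's therapy rows) to
event occurrence (`EVENT_DT`), plus 0.5 — the half-day convention keeps a
same-day onset positive. Records with a partial or missing date are
excluded as `partial_date`/`missing_date`; a non-positive interval is a
data-entry error and is excluded as `negative_or_zero`, never treated as
a negative onset. Exclusions are counted, and included plus excluded
always equals the input count.

Included times are fitted with a two-parameter Weibull: scale
\(\alpha\) (days; the 63.2% quantile of the onset distribution) and
shape \(\beta\). The fit is a profile maximum likelihood: for fixed
\(\beta\) the scale has the closed form
\(\hat\alpha = (\tfrac1n \sum t_i^\beta)^{1/\beta}\), so \(\beta\)
solves a one-dimensional score equation by bracketed root finding —
deterministic, no random initialization. 95% CIs come from the observed
information on the log-parameter scale (back-transformed, so they
respect positivity); this is deterministic and fast, where a bootstrap
would not be. Fewer than 10 records (configurable, mirroring the
convention of fitting only drugs with more than 10 reports) or an
all-identical sample is an error.

The shape classifies the hazard: \(\beta < 1\) with its whole CI below 1
is **early failure** (onset risk concentrated after initiation);
\(\beta > 1\) with the CI above 1 is **wear-out** (risk grows with
cumulative exposure); a CI containing 1 is **random failure**
(indistinguishable from a constant hazard).

Group comparisons use the Kaplan-Meier cumulative incidence
\(1 - S(t)\) and the k-sample Mantel-Cox log-rank test. FAERS onset
records are event-complete by construction — a report exists because the
event happened — so there is no censoring model, the cumulative
incidence equals the ECDF, and the log-rank runs on fully observed
times. Summaries report medians and IQRs as linear-interpolation
(type-7) quantiles in days.

## Descriptive reporting

`summarize_cohort()` produces a clinical Table-1-style summary: age
binned at <18, 18–44, 45–64, 65–74, ≥75; sex out of the full cohort;
countries ranked by count; reporter occupations mapped from the FAERS
codes. Outcomes are tallied once per case with the severity priority
death > life-threatening > disability > hospitalization > congenital
anomaly > intervention-required > other, so outcome percentages sum to
100% of cases with an outcome — the convention implied when published
outcome tables sum to ~100%. `annual_series()` counts reports and death
reports (`DE` among the outcomes) per receipt year (`FDA_DT`), chosen
over the event year because receipt dates are essentially complete;
year-precision dates still contribute.

## The synthetic generator

`generate_faers()` draws cases independently from a
`synthetic_config()`: one primary-suspect drug per case (probability
proportional to configured use), target-event occurrence with probability
`p_event_base * rr[drug]` — the association is injected on the
reporting-ratio scale, which is what disproportionality estimates —
onset from the per-drug Weibull converted to day-precision date pairs, a
configurable fraction of dates degraded to month/year precision to
exercise the exclusion paths, demographics from a configured mixture
(defaults: 55/35/10 female/male/unknown, median age in the mid-50s,
US-dominated reporting, hospitalization the leading outcome — the
profile typical of VTE report cohorts), and duplicate report versions
cloned under a higher `PRIMARYID` with an equal-or-later `FDA_DT`
(equal dates exercise the id tie-break). An association whose scaled
probability would exceed 1 is rejected at validation. Generation is
fully deterministic given the seed and leaves the caller's random stream
untouched.

The ground truth returned alongside the tables (exact per-drug 2×2
counts, per-case onset and demographics, the duplicate map) is what the
tests compare pipeline output against.

What the generator does **not** emulate: co-prescription correlation
(one suspect drug per case by default), free-text noise beyond the
configured synonym list, reporting-rate drift over calendar time,
duplicate versions that differ in content, and within-class correlation
of onset profiles. Passing tests therefore demonstrate that the
pipeline's arithmetic and bookkeeping are correct under the stated
statistical model — not that real FAERS signal lists are clinically
valid, which additionally depends on the PT list, the synonym
dictionary, and confounding that disproportionality cannot remove.

## Test and simulation scale

The bundled test suite exercises the shared synthetic cohort at 10^4
cases, end-to-end detection and null calibration at 10^5 cases (5
injected associations at RR 10 among 50 nulls; 200 null drugs), Weibull
parameter recovery at n = 1000–20 000 over 100 replicates, and the
mixture fit on 5000 simulated pairs — sizes chosen so each check has the
statistical power it needs while the whole suite stays comfortably
desk-scale. The analysis scripts under `analysis/` run the full pipeline
on a 50 000-case cohort with graded association strengths (RR 10 down
to 4); the weakest injected association sits near the detection boundary
of the EBGM05 > 2 criterion, which is the expected behaviour of the
combined rule, whose specificity comes at the price of sensitivity to
weak signals.

## Known limitations

* Disproportionality is hypothesis-generating: reporting odds are not
  incidence, and no stratified or adjusted variants (age/sex-stratified
  MGPS, shrinkage regression) are implemented.
* Partial dates are excluded from onset fits rather than handled by an
  interval-censored likelihood.
* The percentile stratification depends on the floor boundary
  convention; other conventions shift level sizes by one drug near the
  cut points.
* The bundled PT list and the generator's dictionary are stand-ins; real
  studies must supply the licensed MedDRA list and a curated synonym
  dictionary.
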