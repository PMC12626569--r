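# Descriptive reporting: Table-1-style demographic/outcome summary of
# the event cohort and the annual trend of reports and death reports.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
ds <- load_dataset(cfg)

s <- summarize_cohort(ds)
readr::write_csv(as.data.frame(s), file.path(results_dir, "table1.csv"))
cat(sprintf(
  "Event cohort: n = %d; median age %.0f (IQR %.0f-%.0f).\n",
  s$n, s$age$median, s$age$q1, s$age$q3
))
sex <- s$sex$table
cat(sprintf(
  "Sex: %s.\n",
  paste(sprintf("%s %.1f%%", sex$level, sex$pct), collapse = ", ")
))
outc <- s$outcomes$table
lead <- outc[order(-outc$n), ][1, ]
cat(sprintf(
  "Leading outcome: %s (%.1f%% of %d with an outcome).\n",
  lead$level, lead$pct, s$outcomes$available_n
))

annual <- annual_series(ds)
readr::write_csv(annual, file.path(results_dir, "annual_series.csv"))
cat(sprintf(
  "Annual series spans %d-%d; deaths never exceed totals: %s.\n",
  min(annual$year), max(annual$year),
  all(annual$death_reports <= annual$total_reports)
))
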