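# Build the analysis cohort: event-positive cases via the VTE PT list,
# primary-suspect drug mentions mapped through the synonym dictionary.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
ds <- load_dataset(cfg)
print(ds)

counts <- tibble::tibble(
  n_total_reports = ds$n_total_reports,
  n_event_reports = length(ds$event_positive),
  n_ps_mentions = nrow(ds$mentions),
  n_distinct_drugs = dplyr::n_distinct(ds$mentions$ingredient),
  n_unmapped_mentions = sum(!ds$mentions$mapped)
)
readr::write_csv(counts, file.path(results_dir, "cohort_counts.csv"))

cat(sprintf(
  "Cohort: %d deduplicated reports, %d event-positive (%.2f%%), %d distinct PS drugs.\n",
  counts$n_total_reports, counts$n_event_reports,
  100 * counts$n_event_reports / counts$n_total_reports,
  counts$n_distinct_drugs
))
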