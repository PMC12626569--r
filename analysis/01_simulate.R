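# Generate the synthetic FAERS-style quarter used by every later script.
# Writes the six "$"-delimited tables plus the generator's ground truth
# (true per-drug 2x2 counts, duplicate map) for later comparison.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
gen <- generate_faers(cfg)

paths <- write_quarter(gen$tables, data_dir, quarter = "24Q1")
jsonlite::write_json(
  list(
    n_cases = gen$truth$n_cases,
    counts = gen$truth$counts,
    n_duplicates = nrow(gen$truth$duplicates)
  ),
  file.path(data_dir, "ground_truth.json"),
  dataframe = "columns", digits = NA
)

cat(sprintf(
  "Simulated %d cases (+%d duplicate report versions) over %d drugs;\n",
  gen$truth$n_cases, nrow(gen$truth$duplicates), nrow(cfg$drugs)
))
cat(sprintf(
  "%d carry injected associations (RR %s); %d cases have the target event.\n",
  sum(cfg$drugs$rr > 1),
  paste(cfg$drugs$rr[cfg$drugs$rr > 1], collapse = "/"),
  sum(gen$truth$cases$event)
))
cat("Tables written to", data_dir, "\n")
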