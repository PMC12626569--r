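#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr n
NULL

#' Run the full pipeline from one configuration
#'
#' Orchestrates ingest (or synthetic generation) -> deduplication ->
#' cohort construction -> disproportionality signals with risk
#' stratification -> time-to-onset analysis -> descriptive summaries,
#' writing every stage's table plus a machine-readable run manifest to
#' `out_dir`.
#'
#' @param config Either a list or a path to a YAML file. Recognised
#'   fields:
#'   * `synthetic`: arguments for [synthetic_config()] (generate data), or
#'   * `input`: named file paths per table role (read real quarters; a
#'     list of such sets is pooled);
#'   * `pt_list`: path to a PT-list CSV (default: the bundled VTE
#'     stand-in, or the generator's target list when synthetic);
#'   * `dictionary`: path to a drug-dictionary CSV (default: the
#'     generator's dictionary when synthetic);
#'   * `thresholds`: overrides for [signal_thresholds()];
#'   * `bcpnn_variant`, `mgps_variant`, `yates`: algorithm switches;
#'   * `min_tto_n`: minimum records per Weibull fit (default 10);
#'   * `seed`: integer seed (synthetic mode).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory artifacts (`dataset`,
#'   `signals`, `tto`, `summary`, `annual`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[faersvte] ", sprintf(...))

  # --- ingest ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    if (!is.null(config$seed)) syn_args$seed <- config$seed
    scfg <- do.call(synthetic_config, syn_args)
    gen <- generate_faers(scfg)
    raw <- gen$tables
    pts <- if (is.null(config$pt_list)) scfg$target_pts else read_pt_list(config$pt_list)
    dict <- if (is.null(config$dictionary)) {
      synthetic_dictionary(scfg)
    } else {
      read_drug_dictionary(config$dictionary)
    }
    log_msg("generated %d synthetic cases (seed %d)", scfg$n_cases, scfg$seed)
  } else if (!is.null(config$input)) {
    inp <- config$input
    raw <- if (is.list(inp[[1L]])) {
      bind_quarters(lapply(inp, read_quarter))
    } else {
      read_quarter(inp)
    }
    if (is.null(config$pt_list)) {
      pts <- read_pt_list(system.file("extdata", "vte_pt_list.csv",
        package = "faersvte", mustWork = TRUE
      ))
    } else {
      pts <- read_pt_list(config$pt_list)
    }
    if (is.null(config$dictionary)) {
      stop("a drug dictionary is required for non-synthetic input", call. = FALSE)
    }
    dict <- read_drug_dictionary(config$dictionary)
    log_msg("read %d raw demo rows", nrow(raw$demo))
  } else {
    stop("config must contain either 'synthetic' or 'input'", call. = FALSE)
  }

  # --- dedup + cohort -------------------------------------------------
  dataset <- build_analysis_dataset(raw, pts, dict)
  dl <- dataset$log$dedup
  log_msg(
    "deduplicated %d rows -> %d cases; %d event-positive",
    dl$n_in, dl$n_out, length(dataset$event_positive)
  )
  readr::write_csv(dl, file.path(out_dir, "dedup_stats.csv"))
  readr::write_csv(
    tibble::tibble(
      n_total_reports = dataset$n_total_reports,
      n_event_reports = length(dataset$event_positive),
      n_ps_mentions = nrow(dataset$mentions),
      n_distinct_drugs = dplyr::n_distinct(dataset$mentions$ingredient)
    ),
    file.path(out_dir, "cohort_counts.csv")
  )

  # --- signals --------------------------------------------------------
  th <- do.call(signal_thresholds, config$thresholds %||% list())
  signals <- compute_signals(
    dataset,
    thresholds = th,
    bcpnn_variant = config$bcpnn_variant %||% "simplified",
    mgps_variant = config$mgps_variant %||% "closed_form",
    yates = config$yates %||% TRUE
  )
  positives <- dplyr::filter(signals, .data$combined_positive)
  log_msg("%d/%d drugs combined-positive", nrow(positives), nrow(signals))
  readr::write_csv(signals, file.path(out_dir, "signals.csv"))
  readr::write_csv(
    stratify_risk(positives),
    file.path(out_dir, "signals_stratified.csv")
  )

  # --- time-to-onset --------------------------------------------------
  min_tto_n <- config$min_tto_n %||% 10L
  tto <- extract_tto(dataset)
  excl <- dplyr::count(tto, .data$exclusion_reason)
  log_msg(
    "TTO: %d records, %d included", nrow(tto), sum(tto$included)
  )
  readr::write_csv(excl, file.path(out_dir, "tto_exclusions.csv"))
  tto_overall <- tto_summary(tto, by = NULL, min_n = min_tto_n)
  tto_drug <- tto_summary(tto, by = "drug", min_n = min_tto_n)
  tto_atc1 <- tto_summary(tto, by = "atc_level1", min_n = min_tto_n)
  readr::write_csv(tto_overall, file.path(out_dir, "tto_overall.csv"))
  readr::write_csv(tto_drug, file.path(out_dir, "tto_drug.csv"))
  readr::write_csv(tto_atc1, file.path(out_dir, "tto_atc1.csv"))
  inc <- dplyr::filter(tto, .data$included, !is.na(.data$atc_level1))
  curves <- lr <- NULL
  if (nrow(inc) && dplyr::n_distinct(inc$atc_level1) >= 2L) {
    gdf <- tibble::tibble(group = inc$atc_level1, tto_days = inc$tto_days)
    curves <- cumulative_incidence(gdf)
    lr <- logrank_test(gdf)
    readr::write_csv(curves, file.path(out_dir, "tto_curves.csv"))
    log_msg(
      "log-rank across ATC level 1: chi2 = %.2f (df %d), p = %.3g",
      lr$statistic, lr$df, lr$p
    )
  }

  # --- descriptives ---------------------------------------------------
  summary_tab <- summarize_cohort(dataset)
  annual <- annual_series(dataset)
  readr::write_csv(as.data.frame(summary_tab), file.path(out_dir, "table1.csv"))
  readr::write_csv(annual, file.path(out_dir, "annual_series.csv"))

  manifest <- list(
    package = "faersvte",
    package_version = as.character(utils::packageVersion("faersvte")),
    r_version = as.character(getRversion()),
    seed = config$seed %||% config$synthetic$seed %||% NA,
    config_hash = rlang::hash(config),
    n_total_reports = dataset$n_total_reports,
    n_event_reports = length(dataset$event_positive),
    n_positive_signals = nrow(positives),
    logrank = lr
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    dataset = dataset, signals = signals, tto = tto,
    tto_overall = tto_overall, tto_drug = tto_drug, tto_atc1 = tto_atc1,
    curves = curves, logrank = lr,
    summary = summary_tab, annual = annual, manifest = manifest
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
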