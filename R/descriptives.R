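age_breaks <- c(-Inf, 18, 45, 65, 75, Inf)
age_labels <- c("<18", "18-44", "45-64", "65-74", ">=75")

outcome_priority <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")
outcome_labels <- c(
  DE = "Death",
  LT = "Life-threatening",
  DS = "Disability",
  HO = "Hospitalization - initial or prolonged",
  CA = "Congenital anomaly",
  RI = "Required intervention to prevent",
  OT = "Other serious (important medical event)"
)

occupation_labels <- c(
  MD = "Physician",
  PH = "Pharmacist",
  CN = "Consumer",
  LW = "Lawyer",
  HP = "Other health-professional",
  OT = "Other"
)

worst_outcome <- function(outcomes) {
  vapply(outcomes, function(o) {
    hit <- outcome_priority[outcome_priority %in% o]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
}

count_pct <- function(x, levels = NULL, denominator = NULL) {
  x <- x[!is.na(x)]
  tab <- if (is.null(levels)) {
    sort(table(x), decreasing = TRUE)
  } else {
    table(factor(x, levels = levels))
  }
  den <- if (is.null(denominator)) length(x) else denominator
  tibble::tibble(
    level = names(tab),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / den
  )
}

#' Demographic and outcome summary of the event cohort
#'
#' The style of a clinical "Table 1": continuous variables as median and
#' interquartile range, categoricals as counts and percentages of the
#' available records. Age is binned into the <18, 18-44, 45-64, 65-74 and
#' >=75 groups; outcomes are tallied one per case using the severity
#' priority death > life-threatening > disability > hospitalization >
#' congenital anomaly > intervention-required > other.
#'
#' @param dataset An `analysis_dataset`.
#' @param event_only Summarise only event-positive cases (default) or the
#'   whole deduplicated dataset.
#' @param top_countries How many countries to report.
#' @return List of class `summary_table` with elements `n`, `age`,
#'   `age_groups`, `weight`, `sex`, `countries`, `outcomes`,
#'   `occupations`; each block carries its `available_n`.
#' @export
summarize_cohort <- function(dataset, event_only = TRUE, top_countries = 5L) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  cases <- dataset$cases
  if (event_only) {
    cases <- dplyr::filter(cases, .data$primaryid %in% dataset$event_positive)
  }
  if (nrow(cases) == 0L) stop("empty cohort", call. = FALSE)

  age <- cases$age_years[!is.na(cases$age_years)]
  wt <- cases$weight_kg[!is.na(cases$weight_kg)]
  bins <- cut(age, breaks = age_breaks, labels = age_labels, right = FALSE)

  outc <- worst_outcome(cases$outcomes)
  outc_tab <- count_pct(outc, levels = outcome_priority)
  outc_tab$level <- unname(outcome_labels[outc_tab$level])

  occ <- cases$reporter_occupation
  occ <- occ[!is.na(occ)]
  occ_lab <- ifelse(occ %in% names(occupation_labels),
    occupation_labels[occ], occupation_labels[["OT"]]
  )

  out <- list(
    n = nrow(cases),
    age = list(
      available_n = length(age),
      median = unname(stats::median(age)),
      q1 = unname(stats::quantile(age, 0.25, type = 7)),
      q3 = unname(stats::quantile(age, 0.75, type = 7))
    ),
    age_groups = c(
      list(available_n = length(age)),
      list(table = count_pct(as.character(bins), levels = age_labels))
    ),
    weight = list(
      available_n = length(wt),
      median = if (length(wt)) unname(stats::median(wt)) else NA_real_,
      q1 = if (length(wt)) unname(stats::quantile(wt, 0.25, type = 7)) else NA_real_,
      q3 = if (length(wt)) unname(stats::quantile(wt, 0.75, type = 7)) else NA_real_
    ),
    sex = list(
      available_n = nrow(cases),
      table = count_pct(cases$sex,
        levels = c("female", "male", "unknown"),
        denominator = nrow(cases)
      )
    ),
    countries = list(
      available_n = sum(!is.na(cases$country)),
      table = utils::head(count_pct(cases$country), top_countries)
    ),
    outcomes = list(
      available_n = sum(!is.na(outc)),
      table = outc_tab
    ),
    occupations = list(
      available_n = length(occ),
      table = count_pct(occ_lab)
    )
  )
  class(out) <- "summary_table"
  out
}

#' Annual counts of reports and death reports
#'
#' Years come from the FDA receipt date (`FDA_DT`) of the retained report,
#' which is complete at least to year precision for parseable dates; a
#' case is a death report when `DE` is among its outcomes. Cases with an
#' invalid receipt date are dropped from the series (counted in the
#' `n_no_year` attribute).
#'
#' @param dataset An `analysis_dataset`.
#' @param event_only Restrict to event-positive cases (default).
#' @return Tibble `year`, `total_reports`, `death_reports`, ordered by
#'   year.
#' @export
annual_series <- function(dataset, event_only = TRUE) {
  cases <- dataset$cases
  if (event_only) {
    cases <- dplyr::filter(cases, .data$primaryid %in% dataset$event_positive)
  }
  year <- cases$fda_dt$year
  death <- vapply(cases$outcomes, function(o) "DE" %in% o, logical(1))
  keep <- !is.na(year)
  out <- tibble::tibble(year = year[keep], death = death[keep]) |>
    dplyr::summarise(
      total_reports = dplyr::n(),
      death_reports = sum(.data$death),
      .by = "year"
    ) |>
    dplyr::arrange(.data$year)
  attr(out, "n_no_year") <- sum(!keep)
  out
}

#' Flatten a summary table to a tidy data frame
#'
#' @param x A `summary_table`.
#' @param ... Unused.
#' @return Tibble `block`, `level`, `n`, `pct` (continuous blocks appear
#'   as median/q1/q3 rows).
#' @export
as.data.frame.summary_table <- function(x, ...) {
  cont <- function(name, blk) {
    tibble::tibble(
      block = name,
      level = c("available_n", "median", "q1", "q3"),
      n = c(blk$available_n, NA, NA, NA),
      pct = NA_real_,
      value = c(NA, blk$median, blk$q1, blk$q3)
    )
  }
  cat_blk <- function(name, blk) {
    dplyr::mutate(blk$table,
      block = name, value = NA_real_,
      .before = 1L
    )
  }
  dplyr::bind_rows(
    cont("age", x$age),
    cat_blk("age_groups", x$age_groups),
    cont("weight", x$weight),
    cat_blk("sex", x$sex),
    cat_blk("countries", x$countries),
    cat_blk("outcomes", x$outcomes),
    cat_blk("occupations", x$occupations)
  ) |> as.data.frame()
}
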