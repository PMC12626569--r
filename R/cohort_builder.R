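#' Normalize a MedDRA term or drug-name string
#'
#' Case-folds, trims, and collapses internal whitespace so that matching is
#' insensitive to the cosmetic variation typical of spontaneous reports.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Read a preferred-term (PT) list
#'
#' The event of interest is defined by a MedDRA PT list supplied as
#' configuration (CSV with columns `pt_code`, `pt_name`). The bundled
#' `vte_pt_list.csv` under `inst/extdata` is an editable stand-in covering
#' the common venous-thromboembolism PTs; it is not the licensed MedDRA
#' dictionary.
#'
#' @param path CSV file path.
#' @return A tibble with integer `pt_code` and normalized `pt_name`.
#' @export
read_pt_list <- function(path) {
  pt <- readr::read_csv(path, col_types = readr::cols(
    pt_code = readr::col_integer(), pt_name = readr::col_character()
  ))
  pt_list(pt$pt_code, pt$pt_name)
}

#' Construct a PT list from vectors
#'
#' @param pt_code Integer codes (may be `NA` when only names are known).
#' @param pt_name Term names; normalized on construction.
#' @return A tibble of class `pt_list`.
#' @export
pt_list <- function(pt_code, pt_name) {
  out <- tibble::tibble(
    pt_code = as.integer(pt_code),
    pt_name = normalize_term(pt_name)
  ) |> dplyr::distinct()
  if (nrow(out) == 0L) stop("PT list is empty", call. = FALSE)
  class(out) <- c("pt_list", class(out))
  out
}

#' Identify event-positive cases
#'
#' A case is event-positive iff at least one of its reaction PTs is on the
#' list — matched by PT code when the REAC table carries one (`PT_CD`
#' column), by normalized name otherwise. Each case counts once no matter
#' how many listed PTs it reports.
#'
#' @param reac Tibble of reaction rows with `PRIMARYID`, `PT`, optionally
#'   `PT_CD`.
#' @param pts A [pt_list()].
#' @return Character vector of unique event-positive `PRIMARYID`s.
#' @export
match_event <- function(reac, pts) {
  if (!inherits(pts, "pt_list") || nrow(pts) == 0L) {
    stop("PT list must be a non-empty pt_list", call. = FALSE)
  }
  by_code <- rep(FALSE, nrow(reac))
  if ("PT_CD" %in% names(reac)) {
    code <- suppressWarnings(as.integer(reac$PT_CD))
    by_code <- !is.na(code) & code %in% stats::na.omit(pts$pt_code)
    has_code <- !is.na(code)
  } else {
    has_code <- rep(FALSE, nrow(reac))
  }
  by_name <- !has_code & normalize_term(reac$PT) %in% pts$pt_name
  unique(reac$PRIMARYID[by_code | by_name])
}

#' Normalize a verbatim drug name for dictionary lookup
#'
#' Verbatim FAERS drug names append dose and form tokens to the product
#' name ("XARELTO 10MG TABLET"). The lookup key is case-folded, trimmed,
#' whitespace-collapsed, with trailing tokens stripped when they are on the
#' suffix list or look like a dose (e.g. `10MG`, `2.5 MG`).
#'
#' @param verbatim Character vector of raw drug names.
#' @param suffixes Tokens to strip from the end (case-insensitive).
#' @return Normalized lookup keys.
#' @export
normalize_drug_name <- function(verbatim,
                                suffixes = c(
                                  "tablet", "tablets", "tab", "capsule",
                                  "capsules", "cap", "injection", "inj",
                                  "solution", "oral", "cream", "patch",
                                  "mg", "mcg", "g", "ml"
                                )) {
  key <- normalize_term(verbatim)
  dose_re <- "^[0-9]+(\\.[0-9]+)?(mg|mcg|g|ml|iu|%)?$"
  vapply(strsplit(key, " ", fixed = TRUE), function(tok) {
    while (length(tok) > 1L &&
      (tok[length(tok)] %in% suffixes || grepl(dose_re, tok[length(tok)]))) {
      tok <- tok[-length(tok)]
    }
    paste(tok, collapse = " ")
  }, character(1))
}

#' Read a drug synonym dictionary
#'
#' CSV with columns `verbatim`, `ingredient`, `atc_code` (7-character ATC;
#' empty for unmapped ingredients). Many verbatim names map to one
#' ingredient; fixed-dose combinations are their own ingredient entries.
#'
#' @param path CSV file path.
#' @return A tibble of class `drug_dictionary` keyed by normalized verbatim
#'   name, with `ingredient`, `atc_code`, `atc_level1`, `atc_level3`.
#' @export
read_drug_dictionary <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  drug_dictionary(d$verbatim, d$ingredient, d$atc_code)
}

#' Construct a drug dictionary from vectors
#'
#' @param verbatim Verbatim names (normalized on construction).
#' @param ingredient Canonical ingredient per verbatim name.
#' @param atc_code 7-character ATC code, or `NA`/empty for unmapped.
#' @return A tibble of class `drug_dictionary`.
#' @export
drug_dictionary <- function(verbatim, ingredient, atc_code = NA_character_) {
  atc <- as.character(atc_code)
  atc[!is.na(atc) & !nzchar(atc)] <- NA_character_
  out <- tibble::tibble(
    key = normalize_drug_name(verbatim),
    ingredient = as.character(ingredient),
    atc_code = atc,
    atc_level1 = substr(atc, 1L, 1L),
    atc_level3 = substr(atc, 1L, 4L)
  ) |> dplyr::distinct(.data$key, .keep_all = TRUE)
  class(out) <- c("drug_dictionary", class(out))
  out
}

#' Map verbatim drug names to canonical ingredients
#'
#' Unmapped names are retained under their normalized verbatim string and
#' flagged (`mapped = FALSE`) — they still contribute to report totals but
#' are excluded from per-drug ranking unless explicitly enabled.
#'
#' @param verbatim Character vector of raw drug names.
#' @param dict A [drug_dictionary()].
#' @return Tibble with `verbatim`, `ingredient`, `atc_code`, `atc_level1`,
#'   `atc_level3`, `mapped`.
#' @export
map_drug <- function(verbatim, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  key <- normalize_drug_name(verbatim)
  i <- match(key, dict$key)
  tibble::tibble(
    verbatim = verbatim,
    ingredient = ifelse(is.na(i), key, dict$ingredient[i]),
    atc_code = dict$atc_code[i],
    atc_level1 = dict$atc_level1[i],
    atc_level3 = dict$atc_level3[i],
    mapped = !is.na(i)
  )
}

#' Restrict drug rows to primary-suspect mentions
#'
#' Only mentions with role code `PS` enter the signal analysis; multiple PS
#' rows of the same ingredient within one case collapse to a single
#' (case, ingredient) mention.
#'
#' @param drug Tibble of drug rows with `PRIMARYID`, `ROLE_COD`,
#'   `DRUGNAME`.
#' @param dict A [drug_dictionary()].
#' @return Tibble of mentions: `primaryid`, `verbatim_name`, `role`,
#'   `ingredient`, `atc_code`, `atc_level1`, `atc_level3`, `mapped`, plus
#'   `drug_seq` when the input carries one (kept for therapy-date linkage).
#' @export
filter_primary_suspect <- function(drug, dict) {
  stopifnot(all(c("PRIMARYID", "ROLE_COD", "DRUGNAME") %in% names(drug)))
  ps <- dplyr::filter(drug, toupper(trimws(.data$ROLE_COD)) == "PS")
  mapped <- map_drug(ps$DRUGNAME, dict)
  out <- tibble::tibble(
    primaryid = ps$PRIMARYID,
    verbatim_name = ps$DRUGNAME,
    role = "PS",
    ingredient = mapped$ingredient,
    atc_code = mapped$atc_code,
    atc_level1 = mapped$atc_level1,
    atc_level3 = mapped$atc_level3,
    mapped = mapped$mapped
  )
  if ("DRUG_SEQ" %in% names(drug)) out$drug_seq <- ps$DRUG_SEQ
  dplyr::slice_head(out, n = 1L, by = c("primaryid", "ingredient"))
}

outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))
  mult <- c(
    YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
    DY = 1 / 365.25, HR = 1 / (24 * 365.25)
  )
  m <- mult[cod]
  m[is.na(m)] <- 1
  out <- age * m
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Assemble the analysis dataset
#'
#' Runs deduplication, builds the per-case table (demographics, dates,
#' outcomes), identifies event-positive cases via the PT list, and
#' restricts drug mentions to primary suspects mapped through the
#' dictionary.
#'
#' @param raw A `raw_tables` object (deduplicated internally if not yet).
#' @param pts A [pt_list()].
#' @param dict A [drug_dictionary()].
#' @return An object of class `analysis_dataset`: list with `cases`
#'   (one row per deduplicated report), `mentions` (PS drug mentions),
#'   `event_positive` (primaryids), `n_total_reports`, `ther` (therapy rows
#'   of surviving cases, for time-to-onset), and `log`.
#' @export
build_analysis_dataset <- function(raw, pts, dict) {
  stopifnot(inherits(raw, "raw_tables"))
  if (is.null(raw$dedup_log)) raw <- apply_dedup(raw)
  demo <- raw$demo

  getcol <- function(tab, col) {
    if (col %in% names(tab)) tab[[col]] else rep(NA_character_, nrow(tab))
  }
  sex_raw <- toupper(trimws(dplyr::coalesce(
    getcol(demo, "SEX"), getcol(demo, "GNDR_COD")
  )))
  outc <- raw$outc
  outcomes <- if (!is.null(outc) && nrow(outc)) {
    outc |>
      dplyr::mutate(code = toupper(trimws(.data$OUTC_COD))) |>
      dplyr::filter(.data$code %in% outcome_codes) |>
      dplyr::distinct(.data$PRIMARYID, .data$code) |>
      dplyr::summarise(outcomes = list(.data$code), .by = "PRIMARYID")
  } else {
    tibble::tibble(PRIMARYID = character(0), outcomes = list())
  }

  cases <- tibble::tibble(
    primaryid = demo$PRIMARYID,
    caseid = demo$CASEID,
    fda_dt = parse_date(getcol(demo, "FDA_DT")),
    event_dt = parse_date(getcol(demo, "EVENT_DT")),
    age_years = age_to_years(getcol(demo, "AGE"), getcol(demo, "AGE_COD")),
    sex = dplyr::case_match(sex_raw, "F" ~ "female", "M" ~ "male",
      .default = "unknown"
    ),
    weight_kg = suppressWarnings(as.numeric(getcol(demo, "WT"))),
    country = toupper(trimws(getcol(demo, "OCCR_COUNTRY"))),
    reporter_occupation = toupper(trimws(getcol(demo, "OCCP_COD")))
  ) |>
    dplyr::left_join(outcomes, by = c(primaryid = "PRIMARYID"))
  cases$outcomes[vapply(cases$outcomes, is.null, logical(1))] <- list(character(0))
  cases$weight_kg[!is.na(cases$weight_kg) & cases$weight_kg <= 0] <- NA_real_
  cases$country[!nzchar(cases$country) | is.na(cases$country)] <- NA_character_
  cases$reporter_occupation[!nzchar(cases$reporter_occupation)] <- NA_character_

  mentions <- filter_primary_suspect(raw$drug, dict)
  event_positive <- match_event(raw$reac, pts)

  out <- list(
    cases = cases,
    mentions = mentions,
    event_positive = event_positive,
    n_total_reports = nrow(cases),
    ther = raw$ther,
    log = list(dedup = raw$dedup_log, files = raw$log)
  )
  class(out) <- "analysis_dataset"
  out
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("<analysis_dataset>\n")
  cat("  reports (deduplicated): ", x$n_total_reports, "\n", sep = "")
  cat("  event-positive reports: ", length(x$event_positive), "\n", sep = "")
  cat(
    "  PS drug mentions: ", nrow(x$mentions), " (",
    dplyr::n_distinct(x$mentions$ingredient), " ingredients)\n",
    sep = ""
  )
  invisible(x)
}
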