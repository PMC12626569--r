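#' Parse FAERS partial dates
#'
#' FAERS date fields are digit strings at day (`YYYYMMDD`), month (`YYYYMM`)
#' or year (`YYYY`) precision, and are frequently empty or malformed. Rather
#' than coercing everything to a `Date` (which would silently drop partial
#' dates), each value is parsed into its components plus a `precision` tag so
#' downstream stages can decide what arithmetic is permitted: time-to-onset
#' needs day precision, the annual trend only a year.
#'
#' @param raw Character vector of raw date strings.
#' @return A tibble with one row per input and columns `year`, `month`, `day`
#'   (integer, `NA` when absent) and `precision` (one of `"day"`, `"month"`,
#'   `"year"`, `"invalid"`). An empty or non-digit string, an impossible
#'   month, or a calendar-invalid day all yield `precision = "invalid"`.
#' @examples
#' parse_date(c("20200110", "202013", "2019", ""))
#' @export
parse_date <- function(raw) {
  raw <- trimws(as.character(raw))
  raw[is.na(raw)] <- ""
  n <- length(raw)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep("invalid", n)

  digits <- grepl("^[0-9]+$", raw)
  n8 <- digits & nchar(raw) == 8L
  n6 <- digits & nchar(raw) == 6L
  n4 <- digits & nchar(raw) == 4L

  year[n4 | n6 | n8] <- as.integer(substr(raw[n4 | n6 | n8], 1L, 4L))
  month[n6 | n8] <- as.integer(substr(raw[n6 | n8], 5L, 6L))
  day[n8] <- as.integer(substr(raw[n8], 7L, 8L))

  precision[n4] <- "year"
  ok_m <- n6 & month >= 1L & month <= 12L
  precision[ok_m] <- "month"
  ok_d <- n8 & month >= 1L & month <= 12L & day >= 1L &
    day <= days_in_month(year, month)
  precision[ok_d] <- "day"

  # month/day slots are only meaningful at the precision that carries them
  bad <- !(precision %in% c("month", "day"))
  month[bad] <- NA_integer_
  day[!(precision == "day")] <- NA_integer_
  year[precision == "invalid"] <- NA_integer_

  tibble::tibble(year = year, month = month, day = day, precision = precision)
}

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  idx <- as.integer(month)
  idx[is.na(idx) | idx < 1L | idx > 12L] <- NA_integer_
  out <- dm[idx]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  out[!is.na(out) & !is.na(leap) & leap & month == 2L] <- 29L
  out
}

#' Sortable key for a partial date
#'
#' Orders partial dates by `(year, month, day)` with absent components
#' filled with zero, so a month-precision date sorts before any day of that
#' month. Invalid dates get `NA`.
#'
#' @param pd A tibble as returned by [parse_date()], or a raw character
#'   vector (parsed first).
#' @return Integer vector `year * 10000 + month * 100 + day`.
#' @export
partial_date_key <- function(pd) {
  if (!is.data.frame(pd)) pd <- parse_date(pd)
  key <- pd$year * 10000L +
    ifelse(is.na(pd$month), 0L, pd$month) * 100L +
    ifelse(is.na(pd$day), 0L, pd$day)
  key[pd$precision == "invalid"] <- NA_integer_
  key
}

#' Convert day-precision partial dates to Date
#'
#' @param pd A tibble as returned by [parse_date()].
#' @return A `Date` vector; `NA` wherever precision is not `"day"`.
#' @export
partial_date_as_date <- function(pd) {
  out <- rep(as.Date(NA), nrow(pd))
  i <- pd$precision == "day"
  out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i], pd$day[i]))
  out
}

#' Read one FAERS-style "$"-delimited table
#'
#' The quarterly ASCII releases are header-first files with fields separated
#' by a literal `$`. Input is decoded as Latin-1 (the releases contain
#' non-UTF-8 bytes). Rows whose field count disagrees with the header are
#' skipped and counted, never silently dropped; the skip count is attached
#' to the result.
#'
#' @param path Path to the file.
#' @param required_cols Columns that must be present in the header; a missing
#'   one is a hard error naming the file and column. Defaults to
#'   `PRIMARYID` and `CASEID`.
#' @return A tibble of character columns (header names upper-cased), with
#'   attributes `n_read` (data lines seen) and `n_skipped`.
#' @export
read_faers_table <- function(path, required_cols = c("PRIMARYID", "CASEID")) {
  if (!file.exists(path)) {
    stop("FAERS table not found: ", path, call. = FALSE)
  }
  con <- file(path, open = "r", encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    stop("empty file (no header line): ", path, call. = FALSE)
  }
  header <- toupper(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  for (col in toupper(required_cols)) {
    if (!col %in% header) {
      stop("file ", path, " is missing mandatory column ", col, call. = FALSE)
    }
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field; pad rows that are one short with ""
  lens <- lengths(parts)
  trail <- lens == length(header) - 1L & endsWith(body, "$")
  parts[trail] <- lapply(parts[trail], function(p) c(p, ""))
  lens[trail] <- length(header)
  ok <- lens == length(header)
  n_skipped <- sum(!ok)
  mat <- do.call(rbind, parts[ok])
  tab <- if (is.null(mat)) {
    stats::setNames(
      tibble::as_tibble(lapply(header, function(x) character(0)), .name_repair = "minimal"),
      header
    )
  } else {
    colnames(mat) <- header
    tibble::as_tibble(mat)
  }
  attr(tab, "n_read") <- length(body)
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Read a FAERS-style quarter into the raw-tables container
#'
#' @param paths Named list/vector of file paths; recognised names are
#'   `demo`, `drug`, `reac`, `ther`, `outc`, `rpsr` (case-insensitive).
#'   `demo`, `drug` and `reac` are mandatory for any analysis; the others
#'   may be absent.
#' @return An object of class `raw_tables`: a list with one tibble per
#'   table plus a `log` tibble of per-file row and skip counts.
#' @export
read_quarter <- function(paths) {
  names(paths) <- tolower(names(paths))
  known <- c("demo", "drug", "reac", "ther", "outc", "rpsr")
  unknown <- setdiff(names(paths), known)
  if (length(unknown)) {
    stop("unknown table role(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  tabs <- lapply(paths, read_faers_table)
  log <- tibble::tibble(
    table = names(tabs),
    file = unname(unlist(paths)),
    n_read = vapply(tabs, function(t) attr(t, "n_read"), integer(1)),
    n_kept = vapply(tabs, nrow, integer(1)),
    n_skipped = vapply(tabs, function(t) attr(t, "n_skipped"), integer(1))
  )
  out <- c(tabs, list(log = log))
  class(out) <- "raw_tables"
  out
}

#' Combine raw-tables objects from several quarters
#'
#' Row-binds each table across quarters (the quarterly files share one
#' schema); logs are concatenated.
#'
#' @param ... `raw_tables` objects, or a single list of them.
#' @return A pooled `raw_tables` object.
#' @export
bind_quarters <- function(...) {
  qs <- list(...)
  if (length(qs) == 1L && !inherits(qs[[1L]], "raw_tables")) qs <- qs[[1L]]
  stopifnot(all(vapply(qs, inherits, logical(1), "raw_tables")))
  roles <- unique(unlist(lapply(qs, function(q) setdiff(names(q), "log"))))
  out <- lapply(roles, function(r) {
    dplyr::bind_rows(lapply(qs, function(q) q[[r]]))
  })
  names(out) <- roles
  out$log <- dplyr::bind_rows(lapply(qs, function(q) q$log))
  class(out) <- "raw_tables"
  out
}

#' Deduplicate demographic rows by the FDA rule
#'
#' FAERS carries multiple versions of the same safety report. Following the
#' FDA-recommended rule, one row per `CASEID` survives: the one with the
#' latest `FDA_DT`, ties broken by the highest `PRIMARYID`. Equivalently,
#' candidates are sorted by (`FDA_DT` ascending, `PRIMARYID` ascending) and
#' the last is kept. `PRIMARYID` is compared numerically when every id in
#' the table is all-digits, lexicographically otherwise. Partial `FDA_DT`s
#' order by (year, month zero-filled, day zero-filled); a `CASEID` whose
#' candidates all have unparseable `FDA_DT` keeps the highest `PRIMARYID`
#' and is counted in the attached log.
#'
#' @param demo Tibble of raw DEMO rows with at least `PRIMARYID`, `CASEID`,
#'   `FDA_DT` columns.
#' @return The surviving rows (one per `CASEID`), with attribute `dedup_log`
#'   listing input/output counts and the number of all-invalid-date cases.
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("PRIMARYID", "CASEID", "FDA_DT") %in% names(demo)))
  fda_key <- partial_date_key(demo$FDA_DT)
  pid <- demo$PRIMARYID
  pid_ord <- if (all(grepl("^[0-9]+$", pid))) as.numeric(pid) else xtfrm(pid)

  n_allbad <- demo |>
    dplyr::mutate(.bad = is.na(fda_key)) |>
    dplyr::summarise(all_bad = all(.data$.bad), .by = "CASEID") |>
    dplyr::pull(.data$all_bad) |>
    sum()
  if (n_allbad > 0L) {
    warning(n_allbad, " CASEID(s) had no parseable FDA_DT; kept highest PRIMARYID",
      call. = FALSE
    )
  }

  keep <- demo |>
    dplyr::mutate(
      .fda = dplyr::coalesce(fda_key, -1L),
      .pid = pid_ord
    ) |>
    dplyr::arrange(.data$.fda, .data$.pid) |>
    dplyr::slice_tail(n = 1L, by = "CASEID") |>
    dplyr::select(-".fda", -".pid")

  attr(keep, "dedup_log") <- tibble::tibble(
    n_in = nrow(demo),
    n_out = nrow(keep),
    n_caseids = dplyr::n_distinct(demo$CASEID),
    n_allbad_dates = n_allbad
  )
  keep
}

#' Restrict raw tables to the deduplicated case set
#'
#' Drops DRUG/REAC/THER/OUTC/RPSR rows whose `PRIMARYID` did not survive
#' deduplication of DEMO.
#'
#' @param raw A `raw_tables` object.
#' @return A `raw_tables` object whose `demo` is deduplicated and whose
#'   other tables only contain surviving `PRIMARYID`s; dedup log attached
#'   as `raw$dedup_log`.
#' @export
apply_dedup <- function(raw) {
  stopifnot(inherits(raw, "raw_tables"), !is.null(raw$demo))
  demo <- deduplicate(raw$demo)
  surv <- demo$PRIMARYID
  out <- raw
  out$demo <- demo
  for (r in intersect(c("drug", "reac", "ther", "outc", "rpsr"), names(raw))) {
    out[[r]] <- dplyr::filter(raw[[r]], .data$PRIMARYID %in% surv)
  }
  out$dedup_log <- attr(demo, "dedup_log")
  out
}
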