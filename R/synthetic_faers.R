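#' Default synthetic drug panel
#'
#' A panel of fictitious ingredients for the generator: each has three
#' verbatim synonyms (brand-like, generic-like, coded), an ATC level-1
#' class cycled over the classes most represented among thromboembolism
#' signals (L, G, B, N, C), a background use probability, a per-drug
#' Weibull onset model, and a true reporting ratio (`rr = 1` for null
#' drugs).
#'
#' @param n_drugs Total number of drugs.
#' @param n_assoc How many carry a true drug-event association.
#' @param rr Reporting ratio of the associated drugs.
#' @param use_prob Background exposure probability per drug (recycled);
#'   default equal shares.
#' @param tto_alpha,tto_beta Weibull scale (days) and shape per drug
#'   (recycled); defaults span early (beta < 1) through wear-out
#'   (beta > 1) onset profiles.
#' @return Tibble usable as the `drugs` field of [synthetic_config()].
#' @export
synthetic_drug_panel <- function(n_drugs = 20L, n_assoc = 3L, rr = 8,
                                 use_prob = NULL,
                                 tto_alpha = c(120, 30, 365, 60, 10),
                                 tto_beta = c(0.65, 1, 1.5, 0.8, 2)) {
  stopifnot(n_assoc <= n_drugs)
  ing <- sprintf("drug%03d", seq_len(n_drugs))
  atc1 <- rep(c("L", "G", "B", "N", "C"), length.out = n_drugs)
  tibble::tibble(
    ingredient = ing,
    synonyms = lapply(seq_len(n_drugs), function(i) {
      c(ing[i], toupper(paste0(ing[i], "brand")), paste0(ing[i], " xr"))
    }),
    atc_code = sprintf(
      "%s01A%s%02d", atc1,
      LETTERS[(seq_len(n_drugs) - 1L) %% 26L + 1L],
      (seq_len(n_drugs) - 1L) %% 99L + 1L
    ),
    atc_level1 = atc1,
    use_prob = rep_len(if (is.null(use_prob)) 1 / n_drugs else use_prob, n_drugs),
    tto_alpha = rep_len(tto_alpha, n_drugs),
    tto_beta = rep_len(tto_beta, n_drugs),
    rr = c(rep(rr, n_assoc), rep(1, n_drugs - n_assoc))
  )
}

#' Bundled stand-in PT list for venous thromboembolism
#'
#' The common VTE preferred terms with synthetic codes — a clearly marked
#' editable stand-in for a licensed MedDRA PT list (see
#' `inst/extdata/vte_pt_list.csv` for the file form).
#'
#' @return A [pt_list()].
#' @export
default_vte_pt_list <- function() {
  pt_list(
    pt_code = c(
      10051055, 10037377, 10047249, 10014523,
      10034272, 10057945, 10037437
    ),
    pt_name = c(
      "Deep vein thrombosis", "Pulmonary embolism", "Venous thrombosis",
      "Embolism venous", "Pelvic venous thrombosis",
      "Venous thrombosis limb", "Pulmonary thrombosis"
    )
  )
}

background_pts <- c(
  "Nausea", "Headache", "Dizziness", "Fatigue", "Rash",
  "Diarrhoea", "Vomiting", "Pyrexia", "Pruritus", "Arthralgia"
)

#' Configuration of the synthetic FAERS generator
#'
#' Defines the study conditions emulated by the generator: cohort size,
#' duplicate-report fraction, the drug panel with injected association
#' strengths and per-drug Weibull onset models, the base probability of
#' the target event among unexposed cases, the fraction of dates degraded
#' to partial precision, and the demographic mixture (defaults follow the
#' demographic profile typical of VTE report cohorts: 55/35/10
#' female/male/unknown, median age in the mid-50s, US-dominated reporting,
#' hospitalization the leading outcome).
#'
#' @param n_cases Number of distinct cases (CASEIDs) to generate.
#' @param duplicate_fraction Fraction of cases that also get a second,
#'   later report version (same CASEID, higher PRIMARYID).
#' @param drugs Drug panel tibble (see [synthetic_drug_panel()]).
#' @param target_pts A [pt_list()] naming the event-defining PTs.
#' @param p_event_base Probability of the target event for a case exposed
#'   to a null drug; exposed-to-associated cases get `p_event_base * rr`.
#' @param degrade_frac Fraction of event/start dates degraded to month or
#'   year precision (half each), to exercise time-to-onset exclusions.
#' @param start_years Calendar-year range for therapy start dates.
#' @param demographics List of sampling probabilities (see defaults).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `synthetic_config` (validated).
#' @export
synthetic_config <- function(n_cases = 20000L,
                             duplicate_fraction = 0.05,
                             drugs = synthetic_drug_panel(),
                             target_pts = default_vte_pt_list(),
                             p_event_base = 0.01,
                             degrade_frac = 0.10,
                             start_years = c(2004L, 2023L),
                             demographics = list(
                               sex = c(female = 0.55, male = 0.35, unknown = 0.10),
                               age_mean = 54, age_sd = 19, age_missing = 0.29,
                               weight_meanlog = log(80), weight_sdlog = 0.30,
                               weight_missing = 0.80,
                               countries = c(
                                 US = 0.57, FR = 0.061, DE = 0.053, CA = 0.052,
                                 GB = 0.051, JP = 0.05, IT = 0.04, OTH = 0.123
                               ),
                               country_missing = 0.05,
                               outcomes = c(
                                 HO = 0.45, OT = 0.32, DE = 0.14, LT = 0.083,
                                 DS = 0.008, RI = 0.002, CA = 0.0003
                               ),
                               outcome_missing = 0.014,
                               occupations = c(
                                 MD = 0.38, CN = 0.29, HP = 0.19, PH = 0.073,
                                 LW = 0.07
                               ),
                               occupation_missing = 0.127
                             ),
                             seed = 20240901L) {
  cfg <- list(
    n_cases = as.integer(n_cases),
    duplicate_fraction = duplicate_fraction,
    drugs = drugs,
    target_pts = target_pts,
    p_event_base = p_event_base,
    degrade_frac = degrade_frac,
    start_years = as.integer(start_years),
    demographics = demographics,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_cases > 0L,
    cfg$duplicate_fraction >= 0, cfg$duplicate_fraction <= 1,
    nrow(drugs) > 0L, all(drugs$use_prob > 0),
    all(drugs$rr > 0), all(drugs$tto_alpha > 0), all(drugs$tto_beta > 0),
    p_event_base > 0, degrade_frac >= 0, degrade_frac <= 1
  )
  if (any(p_event_base * drugs$rr > 0.99)) {
    stop("infeasible association: p_event_base * rr exceeds 1 for ",
      paste(drugs$ingredient[p_event_base * drugs$rr > 0.99], collapse = ", "),
      call. = FALSE
    )
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Drug dictionary implied by a synthetic configuration
#'
#' Maps every configured synonym (and the ingredient name itself) to its
#' ingredient and ATC code — the dictionary the cohort builder should use
#' on generated data.
#'
#' @param config A [synthetic_config()].
#' @return A [drug_dictionary()].
#' @export
synthetic_dictionary <- function(config) {
  d <- config$drugs
  drug_dictionary(
    verbatim = unlist(d$synonyms),
    ingredient = rep(d$ingredient, lengths(d$synonyms)),
    atc_code = rep(d$atc_code, lengths(d$synonyms))
  )
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fmt_date <- function(d) format(d, "%Y%m%d")

degrade_dates <- function(x, frac) {
  n <- length(x)
  u <- stats::runif(n)
  x[u < frac / 2] <- substr(x[u < frac / 2], 1L, 6L)
  x[u >= frac / 2 & u < frac] <- substr(x[u >= frac / 2 & u < frac], 1L, 4L)
  x
}

#' Generate a synthetic FAERS-like quarter with ground truth
#'
#' Cases are drawn independently: one primary-suspect drug per case
#' (probability proportional to `use_prob`), target-event occurrence with
#' probability `p_event_base * rr[drug]`, onset times from the per-drug
#' Weibull converted to day-precision `START_DT`/`EVENT_DT` pairs, a
#' configurable fraction of dates degraded to partial precision,
#' demographics from the configured mixture, and duplicate report
#' versions created by cloning a case under a new (higher) `PRIMARYID`
#' with an equal-or-later `FDA_DT`. Fully deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `tables` (a `raw_tables` object: DEMO, DRUG, REAC,
#'   THER, OUTC, RPSR as character tibbles) and `truth` (ground truth:
#'   per-drug 2x2 counts, per-case drug/event/onset assignments, the
#'   duplicate map, and the demographic draw).
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_seed(config$seed, {
    n <- config$n_cases
    d <- config$drugs
    dem <- config$demographics

    caseid <- sprintf("%d", 10000000L + seq_len(n))
    primaryid <- paste0(caseid, "1")

    drug_idx <- sample.int(nrow(d), n, replace = TRUE, prob = d$use_prob)
    p_event <- config$p_event_base * d$rr[drug_idx]
    event <- stats::runif(n) < p_event

    # therapy start uniform over the configured years, onset from the
    # per-drug Weibull; the generated whole-day interval + 0.5 is the
    # ground-truth onset time the pipeline should recover
    day0 <- as.Date(sprintf("%d-01-01", config$start_years[1L]))
    day1 <- as.Date(sprintf("%d-12-31", config$start_years[2L]))
    start_date <- day0 + floor(stats::runif(n) * (as.numeric(day1 - day0) + 1))
    tto_raw <- stats::rweibull(n, shape = d$tto_beta[drug_idx], scale = d$tto_alpha[drug_idx])
    onset_days <- floor(tto_raw)
    event_date <- start_date + ifelse(event, onset_days, floor(stats::rexp(n, 1 / 60)))
    fda_date <- event_date + sample.int(61L, n, replace = TRUE) - 1L

    sex <- sample(names(dem$sex), n, replace = TRUE, prob = dem$sex)
    sex_cod <- c(female = "F", male = "M", unknown = "UNK")[sex]
    age <- round(pmin(pmax(stats::rnorm(n, dem$age_mean, dem$age_sd), 0), 100))
    age_str <- ifelse(stats::runif(n) < dem$age_missing, "", as.character(age))
    wt <- round(stats::rlnorm(n, dem$weight_meanlog, dem$weight_sdlog), 1)
    wt_str <- ifelse(stats::runif(n) < dem$weight_missing, "", as.character(wt))
    country <- sample(names(dem$countries), n, replace = TRUE, prob = dem$countries)
    country[stats::runif(n) < dem$country_missing] <- ""
    occ <- sample(names(dem$occupations), n, replace = TRUE, prob = dem$occupations)
    occ[stats::runif(n) < dem$occupation_missing] <- ""
    outc_cod <- sample(names(dem$outcomes), n, replace = TRUE, prob = dem$outcomes)
    has_outc <- stats::runif(n) >= dem$outcome_missing
    extra_ot <- has_outc & outc_cod != "OT" & stats::runif(n) < 0.15

    start_str <- degrade_dates(fmt_date(start_date), config$degrade_frac)
    event_str <- degrade_dates(fmt_date(event_date), config$degrade_frac)
    fda_str <- fmt_date(fda_date)

    syn_pick <- vapply(seq_len(n), function(i) {
      s <- d$synonyms[[drug_idx[i]]]
      s[(i %% length(s)) + 1L]
    }, character(1))
    with_form <- stats::runif(n) < 0.25
    drugname <- ifelse(with_form, paste(toupper(syn_pick), "10MG TABLET"), syn_pick)

    target_names <- config$target_pts$pt_name
    target_pt <- sample(target_names, n, replace = TRUE)
    bg_pt <- sample(background_pts, n, replace = TRUE)

    demo <- tibble::tibble(
      PRIMARYID = primaryid, CASEID = caseid,
      FDA_DT = fda_str, EVENT_DT = event_str,
      AGE = age_str, AGE_COD = ifelse(nzchar(age_str), "YR", ""),
      SEX = sex_cod,
      WT = wt_str, WT_COD = ifelse(nzchar(wt_str), "KG", ""),
      OCCR_COUNTRY = country, OCCP_COD = occ
    )
    conc <- stats::runif(n) < 0.2
    conc_idx <- ifelse(drug_idx < nrow(d), drug_idx + 1L, 1L)
    drug_tab <- dplyr::bind_rows(
      tibble::tibble(
        PRIMARYID = primaryid, CASEID = caseid, DRUG_SEQ = "1",
        ROLE_COD = "PS", DRUGNAME = drugname
      ),
      tibble::tibble(
        PRIMARYID = primaryid[conc], CASEID = caseid[conc], DRUG_SEQ = "2",
        ROLE_COD = "C", DRUGNAME = d$ingredient[conc_idx[conc]]
      )
    )
    reac <- dplyr::bind_rows(
      tibble::tibble(PRIMARYID = primaryid[event], CASEID = caseid[event], PT = target_pt[event]),
      tibble::tibble(PRIMARYID = primaryid, CASEID = caseid, PT = bg_pt)
    )
    ther <- tibble::tibble(
      PRIMARYID = primaryid, CASEID = caseid, DSG_DRUG_SEQ = "1",
      START_DT = start_str, END_DT = ""
    )
    outc <- dplyr::bind_rows(
      tibble::tibble(PRIMARYID = primaryid[has_outc], CASEID = caseid[has_outc], OUTC_COD = outc_cod[has_outc]),
      tibble::tibble(PRIMARYID = primaryid[extra_ot], CASEID = caseid[extra_ot], OUTC_COD = "OT")
    )
    rpsr <- tibble::tibble(
      PRIMARYID = primaryid, CASEID = caseid,
      RPSR_COD = sample(c("FGN", "HP", "CSM"), n, replace = TRUE)
    )

    # duplicate versions: same CASEID, higher PRIMARYID, FDA_DT moved
    # 0-30 days later (0 exercises the highest-PRIMARYID tie-break)
    n_dup <- round(config$duplicate_fraction * n)
    dup_i <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
    if (length(dup_i)) {
      dup_pid <- paste0(caseid[dup_i], "2")
      dup_fda <- fmt_date(fda_date[dup_i] + sample.int(31L, length(dup_i), replace = TRUE) - 1L)
      clone <- function(tab, idx_rows, new_pid) {
        out <- tab[idx_rows, , drop = FALSE]
        out$PRIMARYID <- new_pid
        out
      }
      demo_dup <- demo[dup_i, , drop = FALSE]
      demo_dup$PRIMARYID <- dup_pid
      demo_dup$FDA_DT <- dup_fda
      demo <- dplyr::bind_rows(demo, demo_dup)
      for (nm in c("drug_tab", "reac", "ther", "outc", "rpsr")) {
        tab <- get(nm)
        rows <- which(tab$CASEID %in% caseid[dup_i])
        new_pid <- paste0(tab$CASEID[rows], "2")
        assign(nm, dplyr::bind_rows(tab, clone(tab, rows, new_pid)))
      }
    }

    fda_year_final <- as.integer(substr(fda_str, 1L, 4L))
    if (length(dup_i)) {
      # the surviving (latest) version of a duplicated case carries the
      # later receipt date; ground truth reports the survivor's year
      fda_year_final[dup_i] <- as.integer(substr(dup_fda, 1L, 4L))
    }

    n_event <- sum(event)
    truth_counts <- tibble::tibble(
      drug = d$ingredient,
      a = as.integer(vapply(seq_len(nrow(d)), function(j) sum(event & drug_idx == j), numeric(1))),
      n_drug = as.integer(tabulate(drug_idx, nrow(d)))
    ) |>
      dplyr::mutate(
        b = .data$n_drug - .data$a,
        c = as.integer(n_event - .data$a),
        d = as.integer(n - .data$n_drug - (n_event - .data$a)),
        N = as.integer(n)
      )

    tables <- list(
      demo = demo, drug = drug_tab, reac = reac,
      ther = ther, outc = outc, rpsr = rpsr,
      log = tibble::tibble(
        table = c("demo", "drug", "reac", "ther", "outc", "rpsr"),
        file = NA_character_,
        n_read = c(nrow(demo), nrow(drug_tab), nrow(reac), nrow(ther), nrow(outc), nrow(rpsr)),
        n_kept = c(nrow(demo), nrow(drug_tab), nrow(reac), nrow(ther), nrow(outc), nrow(rpsr)),
        n_skipped = 0L
      )
    )
    class(tables) <- "raw_tables"

    truth <- list(
      n_cases = n,
      counts = truth_counts,
      cases = tibble::tibble(
        caseid = caseid, primaryid = primaryid,
        drug = d$ingredient[drug_idx], event = event,
        tto_days = onset_days + 0.5,
        start_day_precision = nchar(start_str) == 8L,
        event_day_precision = nchar(event_str) == 8L,
        sex = sex, age = ifelse(nzchar(age_str), age, NA_real_),
        outcome = ifelse(has_outc, outc_cod, NA_character_),
        fda_year = fda_year_final
      ),
      duplicates = {
        dup_caseid <- caseid[dup_i]
        tibble::tibble(
          caseid = dup_caseid,
          primaryid_original = primaryid[dup_i],
          primaryid_duplicate = paste0(dup_caseid, "2")
        )
      }
    )
    list(tables = tables, truth = truth)
  })
}

#' Write tables as a FAERS-style quarter
#'
#' One "$"-delimited file per table with FAERS naming
#' (`DEMO<yyQq>.txt`, ...), header first.
#'
#' @param tables A `raw_tables` object or plain list of tibbles.
#' @param dir Output directory (created if needed).
#' @param quarter Quarter label used in the file names, e.g. `"24Q1"`.
#' @return Named list of file paths suitable for [read_quarter()].
#' @export
write_quarter <- function(tables, dir, quarter = "24Q1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roles <- intersect(c("demo", "drug", "reac", "ther", "outc", "rpsr"), names(tables))
  paths <- stats::setNames(vector("list", length(roles)), roles)
  for (r in roles) {
    tab <- tables[[r]]
    path <- file.path(dir, paste0(toupper(r), quarter, ".txt"))
    lines <- c(
      paste(names(tab), collapse = "$"),
      if (nrow(tab)) do.call(paste, c(unname(as.list(tab)), sep = "$"))
    )
    writeLines(lines, path, useBytes = TRUE)
    paths[[r]] <- path
  }
  paths
}
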