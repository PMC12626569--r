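#' 2x2 contingency table for one drug-event pair
#'
#' The counting unit is the deduplicated case. With `N` total reports,
#' `a` = reports with the target drug as primary suspect AND the event,
#' `b` = drug without the event, `c` = event under any other drug,
#' `d` = neither.
#'
#' @param dataset An `analysis_dataset`.
#' @param drug Ingredient name.
#' @return Named list `(a, b, c, d, N)`.
#' @export
contingency <- function(dataset, drug) {
  tab <- contingency_tables(dataset, drugs = drug, include_unmapped = TRUE)
  if (nrow(tab) == 0L) stop("drug not present in dataset: ", drug, call. = FALSE)
  as.list(tab[1L, c("a", "b", "c", "d", "N")])
}

#' Contingency tables for all (or selected) drugs
#'
#' @param dataset An `analysis_dataset`.
#' @param drugs Ingredients to tabulate; default all in the dataset.
#' @param include_unmapped Include names that failed dictionary mapping?
#'   They always contribute to `N`; this flag only controls whether they
#'   get their own row. Default `FALSE`.
#' @return Tibble with `drug`, `atc_code`, `atc_level1`, `atc_level3`,
#'   `a`, `b`, `c`, `d`, `N`.
#' @export
contingency_tables <- function(dataset, drugs = NULL, include_unmapped = FALSE) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  N <- dataset$n_total_reports
  n_event <- length(dataset$event_positive)
  m <- dataset$mentions |>
    dplyr::distinct(.data$primaryid, .data$ingredient, .keep_all = TRUE)
  if (!include_unmapped) m <- dplyr::filter(m, .data$mapped)
  if (!is.null(drugs)) m <- dplyr::filter(m, .data$ingredient %in% drugs)
  m |>
    dplyr::mutate(event = .data$primaryid %in% dataset$event_positive) |>
    dplyr::summarise(
      atc_code = .data$atc_code[1L],
      atc_level1 = .data$atc_level1[1L],
      atc_level3 = .data$atc_level3[1L],
      a = sum(.data$event),
      n_drug = dplyr::n(),
      .by = "ingredient"
    ) |>
    dplyr::transmute(
      drug = .data$ingredient,
      atc_code = .data$atc_code,
      atc_level1 = .data$atc_level1,
      atc_level3 = .data$atc_level3,
      a = as.integer(.data$a),
      b = as.integer(.data$n_drug - .data$a),
      c = as.integer(n_event - .data$a),
      d = as.integer(N - .data$n_drug - (n_event - .data$a)),
      N = as.integer(N)
    )
}

correct_zero_cells <- function(a, b, c, d) {
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  add <- ifelse(corrected, 0.5, 0)
  list(a = a + add, b = b + add, c = c + add, d = d + add, corrected = corrected)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = ad / bc`; the 100(1-2*pnorm(-z))% CI is
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane continuity correction (+0.5 to all four cells) is applied
#' and the result flagged.
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @param z Normal quantile for the CI (1.96 two-sided 95%).
#' @return Tibble `ror`, `ci_low`, `ci_high`, `corrected`.
#' @export
ror <- function(a, b, c, d, z = 1.96) {
  cc <- correct_zero_cells(a, b, c, d)
  est <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  tibble::tibble(
    ror = est,
    ci_low = exp(log(est) - z * se),
    ci_high = exp(log(est) + z * se),
    corrected = cc$corrected
  )
}

#' Proportional reporting ratio and Yates chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-square is the 2x2 statistic with
#' Yates continuity correction, `sum((|O-E| - 0.5)^2 / E)` with expecteds
#' from the margins (the conventional companion of the PRR >= 2 criterion);
#' set `yates = FALSE` for the uncorrected Pearson statistic.
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return Tibble `prr`, `chi2`.
#' @export
prr_chi2 <- function(a, b, c, d, yates = TRUE) {
  if (any(a + b <= 0)) stop("zero drug margin (a+b = 0)", call. = FALSE)
  if (any(c + d <= 0)) stop("zero comparator margin (c+d = 0)", call. = FALSE)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- mapply(function(a, b, c, d) {
    m <- matrix(c(a, c, b, d), nrow = 2L)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      return(NaN)
    }
    unname(suppressWarnings(
      stats::chisq.test(m, correct = yates)$statistic
    ))
  }, a, b, c, d)
  tibble::tibble(prr = prr, chi2 = chi2)
}

#' BCPNN prior hyperparameters and MGPS initial values
#'
#' Defaults follow the original BCPNN beta/Dirichlet prior
#' (`alpha = beta = 2`, `alpha1 = beta1 = 1`, `gamma11 = 1`) and the
#' customary gamma-Poisson mixture starting point for the MGPS fit.
#'
#' @param bcpnn_alpha,bcpnn_beta Marginal beta-prior totals.
#' @param bcpnn_alpha1,bcpnn_beta1 Marginal beta-prior successes.
#' @param bcpnn_gamma11 Joint-cell prior count.
#' @param mgps_init Numeric vector `(alpha1, beta1, alpha2, beta2, P)` used
#'   to start the mixture-likelihood optimisation.
#' @return List of class `prior_config`.
#' @export
prior_config <- function(bcpnn_alpha = 2, bcpnn_beta = 2,
                         bcpnn_alpha1 = 1, bcpnn_beta1 = 1,
                         bcpnn_gamma11 = 1,
                         mgps_init = c(
                           alpha1 = 0.2, beta1 = 0.1,
                           alpha2 = 2, beta2 = 4, P = 1 / 3
                         )) {
  stopifnot(
    bcpnn_alpha > 0, bcpnn_beta > 0, bcpnn_alpha1 > 0, bcpnn_beta1 > 0,
    bcpnn_gamma11 > 0, all(mgps_init[1:4] > 0),
    mgps_init[5] > 0, mgps_init[5] < 1
  )
  structure(
    list(
      bcpnn_alpha = bcpnn_alpha, bcpnn_beta = bcpnn_beta,
      bcpnn_alpha1 = bcpnn_alpha1, bcpnn_beta1 = bcpnn_beta1,
      bcpnn_gamma11 = bcpnn_gamma11, mgps_init = mgps_init
    ),
    class = "prior_config"
  )
}

#' BCPNN information component
#'
#' The information component is a shrunk log2 observed-to-expected
#' reporting ratio. Two variants are provided:
#'
#' * `"simplified"` (default): point `IC = log2(aN / ((a+b)(a+c)))` with
#'   `IC025 = IC - 2 * sqrt(V)`, `V` the three-term posterior variance of
#'   the beta/Dirichlet model below.
#' * `"bate"`: full posterior moments — `E(IC)` and `V(IC)` from the
#'   beta-binomial posterior with the `prior_config` hyperparameters, the
#'   joint prior total `gamma` chosen so that `E(IC) = 0` at independence;
#'   `IC025 = E(IC) - 2 * sqrt(V(IC))`.
#'
#' IC is in log2 units. With `a = 0` the simplified point IC is `-Inf`
#' (no observed reports); the bate variant shrinks it to a finite value.
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @param prior A [prior_config()].
#' @param variant `"simplified"` or `"bate"`.
#' @return Tibble `ic`, `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d, prior = prior_config(),
                     variant = c("simplified", "bate")) {
  variant <- match.arg(variant)
  N <- a + b + c + d
  if (any(N <= 0)) stop("empty dataset (N = 0)", call. = FALSE)
  if (any(a + b <= 0) || any(a + c <= 0)) {
    stop("zero margin: a+b and a+c must be positive", call. = FALSE)
  }
  al <- prior$bcpnn_alpha
  be <- prior$bcpnn_beta
  al1 <- prior$bcpnn_alpha1
  be1 <- prior$bcpnn_beta1
  g11 <- prior$bcpnn_gamma11
  gamma <- g11 * (N + al) * (N + be) / ((a + b + al1) * (a + c + be1))
  v <- (1 / log(2)^2) * (
    (N - a + gamma - g11) / ((a + g11) * (1 + N + gamma)) +
      (N - (a + b) + al - al1) / ((a + b + al1) * (1 + N + al)) +
      (N - (a + c) + be - be1) / ((a + c + be1) * (1 + N + be))
  )
  ic <- switch(variant,
    simplified = log2(a * N / ((a + b) * (a + c))),
    bate = log2(
      (a + g11) * (N + al) * (N + be) /
        ((N + gamma) * (a + b + al1) * (a + c + be1))
    )
  )
  tibble::tibble(ic = ic, ic025 = ic - 2 * sqrt(v))
}

nb_mix_nll <- function(theta, a, E) {
  a1 <- exp(theta[1L])
  b1 <- exp(theta[2L])
  a2 <- exp(theta[3L])
  b2 <- exp(theta[4L])
  P <- stats::plogis(theta[5L])
  nll <- suppressWarnings({
    l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
    l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
    m <- pmax(l1, l2)
    -sum(m + log(P * exp(l1 - m) + (1 - P) * exp(l2 - m)))
  })
  if (!is.finite(nll)) 1e10 else nll
}

#' MGPS empirical-Bayes gamma-Poisson shrinkage
#'
#' For each pair the observed count `a` is modelled as Poisson with mean
#' `lambda * E`, `E = (a+b)(a+c)/N` the expected count under independence,
#' and `lambda` drawn from a two-component gamma mixture prior.
#'
#' * `variant = "em"`: the mixture prior `(alpha1, beta1, alpha2, beta2, P)`
#'   is fitted by maximizing the negative-binomial marginal likelihood over
#'   all supplied pairs (quasi-Newton on transformed parameters — the
#'   direct-optimisation route to the same maximum as EM); `EBGM` is the
#'   geometric mean of the posterior `lambda` and `EBGM05` its posterior
#'   5th percentile, both from the mixture-of-gammas posterior.
#' * `variant = "closed_form"` (default): `EBGM = aN / ((a+b)(a+c))` with
#'   `EBGM05 = exp(ln EBGM - 1.645 * sqrt(1/a + 1/b + 1/c + 1/d))` (zero
#'   cells continuity-corrected as for the ROR).
#'
#' @param a,b,c,d Cell counts for every drug-event pair under study (the
#'   `em` variant needs the full set, not one table at a time).
#' @param prior A [prior_config()]; `mgps_init` starts the fit.
#' @param variant `"closed_form"` or `"em"`.
#' @param max_iter Optimiser iteration cap; non-convergence is an error
#'   carrying the last parameter values.
#' @return Tibble `ebgm`, `ebgm05`; for `"em"` the fitted prior is attached
#'   as attribute `mixture` (`alpha1`, `beta1`, `alpha2`, `beta2`, `P`).
#' @export
mgps_ebgm <- function(a, b, c, d, prior = prior_config(),
                      variant = c("closed_form", "em"), max_iter = 500L) {
  variant <- match.arg(variant)
  N <- a + b + c + d
  if (variant == "closed_form") {
    cc <- correct_zero_cells(a, b, c, d)
    Ncc <- cc$a + cc$b + cc$c + cc$d
    ebgm <- cc$a * Ncc / ((cc$a + cc$b) * (cc$a + cc$c))
    se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
    return(tibble::tibble(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.645 * se)))
  }
  E <- (a + b) * (a + c) / N
  # the marginal likelihood is multi-modal in the transformed parameters;
  # take the best of several deterministic starting points
  starts <- list(
    prior$mgps_init,
    c(alpha1 = 1, beta1 = 1, alpha2 = 2, beta2 = 0.2, P = 0.8),
    c(alpha1 = 2, beta1 = 2, alpha2 = 1, beta2 = 0.1, P = 0.5)
  )
  fit <- NULL
  for (init in starts) {
    theta0 <- c(log(init[1:4]), stats::qlogis(init[[5L]]))
    cand <- stats::optim(theta0, nb_mix_nll,
      a = a, E = E, method = "BFGS",
      control = list(maxit = max_iter, reltol = 1e-12)
    )
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  pars <- c(exp(fit$par[1:4]), stats::plogis(fit$par[5L]))
  names(pars) <- c("alpha1", "beta1", "alpha2", "beta2", "P")
  # order components by their prior means so component 1 is the null-like one
  if (pars[["alpha1"]] / pars[["beta1"]] > pars[["alpha2"]] / pars[["beta2"]]) {
    pars <- c(
      alpha1 = pars[["alpha2"]], beta1 = pars[["beta2"]],
      alpha2 = pars[["alpha1"]], beta2 = pars[["beta1"]],
      P = 1 - pars[["P"]]
    )
  }
  if (fit$convergence != 0L) {
    stop(
      "MGPS mixture fit did not converge; last parameters: ",
      paste(sprintf("%s=%.4g", names(pars), pars), collapse = ", "),
      call. = FALSE
    )
  }
  a1 <- pars[[1L]]
  b1 <- pars[[2L]]
  a2 <- pars[[3L]]
  b2 <- pars[[4L]]
  P <- pars[[5L]]
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  q1 <- P * exp(l1 - m) / (P * exp(l1 - m) + (1 - P) * exp(l2 - m))
  # posterior: q1 * Gamma(a1 + a, b1 + E) + (1 - q1) * Gamma(a2 + a, b2 + E)
  elog <- q1 * (digamma(a1 + a) - log(b1 + E)) +
    (1 - q1) * (digamma(a2 + a) - log(b2 + E))
  ebgm <- exp(elog)
  ebgm05 <- mapply(function(a_i, E_i, q_i) {
    f <- function(x) {
      q_i * stats::pgamma(x, a1 + a_i, rate = b1 + E_i) +
        (1 - q_i) * stats::pgamma(x, a2 + a_i, rate = b2 + E_i) - 0.05
    }
    lo <- min(
      stats::qgamma(0.05, a1 + a_i, rate = b1 + E_i),
      stats::qgamma(0.05, a2 + a_i, rate = b2 + E_i)
    )
    hi <- max(
      stats::qgamma(0.05, a1 + a_i, rate = b1 + E_i),
      stats::qgamma(0.05, a2 + a_i, rate = b2 + E_i)
    )
    if (f(lo) >= 0) return(lo)
    if (f(hi) <= 0) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, a, E, q1)
  out <- tibble::tibble(ebgm = ebgm, ebgm05 = ebgm05)
  attr(out, "mixture") <- pars
  out
}

#' Default positive-signal thresholds
#'
#' The canonical criteria in FAERS disproportionality studies of this
#' design: ROR requires `a >= 3` reports and a lower CI bound above 1; PRR
#' requires `a >= 3`, `PRR >= 2` and chi-square `>= 4`; BCPNN requires
#' `IC025 > 0`; MGPS requires `EBGM05 > 2`.
#'
#' @param ror_min_a,ror_ci_low,prr_min_a,prr_min,chi2_min,ic025_min,ebgm05_min
#'   Criterion cut-offs.
#' @return Named list of thresholds.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_ci_low = 1,
                              prr_min_a = 3, prr_min = 2, chi2_min = 4,
                              ic025_min = 0, ebgm05_min = 2) {
  list(
    ror_min_a = ror_min_a, ror_ci_low = ror_ci_low,
    prr_min_a = prr_min_a, prr_min = prr_min, chi2_min = chi2_min,
    ic025_min = ic025_min, ebgm05_min = ebgm05_min
  )
}

#' Apply the four-criteria combined signal rule
#'
#' A pair is a positive signal only when all four algorithmic criteria hold
#' simultaneously.
#'
#' @param metrics Tibble with columns `a`, `ror_ci_low` (or `ci_low`),
#'   `prr`, `chi2`, `ic025`, `ebgm05`.
#' @param thresholds A [signal_thresholds()] list.
#' @return The input with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `combined_positive`.
#' @export
combined_signal <- function(metrics, thresholds = signal_thresholds()) {
  ci_low <- if ("ror_ci_low" %in% names(metrics)) {
    metrics$ror_ci_low
  } else {
    metrics$ci_low
  }
  th <- thresholds
  metrics$flag_ror <- metrics$a >= th$ror_min_a & ci_low > th$ror_ci_low
  metrics$flag_prr <- metrics$a >= th$prr_min_a &
    metrics$prr >= th$prr_min & metrics$chi2 >= th$chi2_min
  metrics$flag_bcpnn <- metrics$ic025 > th$ic025_min
  metrics$flag_mgps <- metrics$ebgm05 > th$ebgm05_min
  metrics$combined_positive <- metrics$flag_ror & metrics$flag_prr &
    metrics$flag_bcpnn & metrics$flag_mgps
  metrics
}

#' A/B/C/D risk stratification by ROR percentile
#'
#' Positive-signal drugs are ranked by ROR descending (ties: larger `a`
#' first, then drug id) and split at the top 5%, 6-20%, 21-50% and
#' 51-100% of ranks. With `n` drugs the boundaries are the floors of the
#' cumulative ranks: A = ranks `1..floor(0.05 n)`, B to `floor(0.20 n)`,
#' C to `floor(0.50 n)`, D the rest.
#'
#' @param signals Tibble of positive signals with columns `drug`, `ror`,
#'   `a`.
#' @return The input ordered by rank with a `risk_level` factor column
#'   (`A`, `B`, `C`, `D`).
#' @export
stratify_risk <- function(signals) {
  if (nrow(signals) == 0L) {
    signals$risk_level <- factor(character(0), levels = c("A", "B", "C", "D"))
    return(signals)
  }
  out <- signals[order(-signals$ror, -signals$a, signals$drug), , drop = FALSE]
  n <- nrow(out)
  k <- floor(c(0.05, 0.20, 0.50) * n)
  rk <- seq_len(n)
  lev <- dplyr::case_when(
    rk <= k[1L] ~ "A",
    rk <= k[2L] ~ "B",
    rk <= k[3L] ~ "C",
    .default = "D"
  )
  out$risk_level <- factor(lev, levels = c("A", "B", "C", "D"))
  out
}

#' Compute the full signal table for a dataset
#'
#' Builds every per-drug 2x2 table, evaluates the four disproportionality
#' algorithms, applies the combined rule and stratifies positives — the
#' data behind a forest plot of signal values.
#'
#' @param dataset An `analysis_dataset`.
#' @param thresholds A [signal_thresholds()] list.
#' @param prior A [prior_config()].
#' @param bcpnn_variant,mgps_variant Algorithm variants (see [bcpnn_ic()],
#'   [mgps_ebgm()]).
#' @param yates Continuity-correct the PRR chi-square?
#' @param include_unmapped Rank drugs that failed dictionary mapping?
#' @param min_a Drop pairs with fewer observed reports than this before
#'   flagging (default 1 = keep all with at least one co-report).
#' @return Tibble of class `signal_table`: one row per drug with counts,
#'   all metrics, per-algorithm flags, `combined_positive` and
#'   `risk_level` (`NA` for non-positives).
#' @export
compute_signals <- function(dataset,
                            thresholds = signal_thresholds(),
                            prior = prior_config(),
                            bcpnn_variant = "simplified",
                            mgps_variant = "closed_form",
                            yates = TRUE,
                            include_unmapped = FALSE,
                            min_a = 1L) {
  tabs <- contingency_tables(dataset, include_unmapped = include_unmapped)
  tabs <- dplyr::filter(tabs, .data$a >= min_a, .data$a + .data$b > 0)
  if (nrow(tabs) == 0L) stop("no drug-event pairs to analyse", call. = FALSE)
  r <- ror(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- prr_chi2(tabs$a, tabs$b, tabs$c, tabs$d, yates = yates)
  bc <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d,
    prior = prior, variant = bcpnn_variant
  )
  eb <- mgps_ebgm(tabs$a, tabs$b, tabs$c, tabs$d,
    prior = prior, variant = mgps_variant
  )
  metrics <- tibble::tibble(
    ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
    ror_corrected = r$corrected,
    prr = p$prr, chi2 = p$chi2,
    ic = bc$ic, ic025 = bc$ic025,
    ebgm = eb$ebgm, ebgm05 = eb$ebgm05
  )
  res <- dplyr::bind_cols(tabs, metrics)
  res <- combined_signal(res, thresholds)
  pos <- stratify_risk(res[res$combined_positive, , drop = FALSE])
  res$risk_level <- factor(NA_character_, levels = c("A", "B", "C", "D"))
  res$risk_level[match(pos$drug, res$drug)] <- pos$risk_level
  res <- res[order(-res$ror), , drop = FALSE]
  class(res) <- c("signal_table", class(res))
  res
}
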