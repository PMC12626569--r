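# One moderately sized synthetic cohort shared across test files.
# 10^4 cases, 20 drugs of which 3 carry a true association (RR = 8,
# expected ~40 co-reports each), 5% duplicate reports, 10% degraded dates.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        n_cases = 10000L,
        drugs = synthetic_drug_panel(n_drugs = 20L, n_assoc = 3L, rr = 8, use_prob = 0.05),
        seed = 7777L
      )
      gen <- generate_faers(cfg)
      ds <- build_analysis_dataset(gen$tables, cfg$target_pts, synthetic_dictionary(cfg))
      cache <<- list(cfg = cfg, gen = gen, dataset = ds)
    }
    cache
  }
})

# independent straight-from-formula evaluations used as oracles
oracle_ror <- function(a, b, c, d, z = 1.96) {
  est <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est, exp(log(est) - z * se), exp(log(est) + z * se))
}

oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))

oracle_yates_chi2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c(
    (a + b) * (a + c), (a + b) * (b + d),
    (c + d) * (a + c), (c + d) * (b + d)
  ) / n
  sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
}

oracle_ic <- function(a, b, c, d) log2(a * (a + b + c + d) / ((a + b) * (a + c)))

oracle_ebgm_cf <- function(a, b, c, d) {
  n <- a + b + c + d
  ebgm <- a * n / ((a + b) * (a + c))
  c(ebgm, exp(log(ebgm) - 1.645 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)))
}
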