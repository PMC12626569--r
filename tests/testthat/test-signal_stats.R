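test_that("ROR and Wald CI reproduce direct arithmetic", {
  r <- ror(5, 95, 100, 9800)
  expect_equal(r$ror, 5.157895, tolerance = 1e-6)
  expect_equal(r$ci_low, 2.05435, tolerance = 1e-4)
  expect_equal(r$ci_high, 12.95090, tolerance = 1e-4)
  expect_false(r$corrected)
  # independence-proportional table
  expect_equal(ror(10, 90, 100, 900)$ror, 1)
  # zero cell: Haldane correction, flagged
  r0 <- ror(0, 100, 100, 9800)
  expect_true(r0$corrected)
  expect_equal(r0$ror, (0.5 * 9800.5) / (100.5 * 100.5))
})

test_that("PRR and Yates chi-square reproduce hand evaluation", {
  p <- prr_chi2(5, 95, 100, 9800)
  expect_equal(p$prr, 4.95, tolerance = 1e-10)
  expect_equal(p$chi2, 11.5717, tolerance = 1e-4)
  # exact independence: PRR 1, clamped Yates statistic 0
  p1 <- prr_chi2(10, 90, 100, 900)
  expect_equal(p1$prr, 1)
  expect_equal(p1$chi2, 0)
  # a = 0 gives PRR 0
  expect_equal(prr_chi2(0, 100, 100, 9800)$prr, 0)
  # zero margins are errors naming the margin
  expect_error(prr_chi2(0, 0, 100, 9800), "a\\+b")
  expect_error(prr_chi2(5, 95, 0, 0), "c\\+d")
})

test_that("ROR/PRR identity holds on non-zero tables", {
  set.seed(21)
  for (i in 1:50) {
    t <- sample(1:500, 4)
    r <- ror(t[1], t[2], t[3], t[4])$ror
    p <- prr_chi2(t[1], t[2], t[3], t[4])$prr
    expect_equal(r, p * ((t[1] + t[2]) / t[2]) / ((t[3] + t[4]) / t[4]),
      tolerance = 1e-12
    )
  }
})

test_that("BCPNN information component matches direct arithmetic and shrinks", {
  # observed component before shrinkage: log2(5e4 / 10500)
  b <- bcpnn_ic(5, 95, 100, 9800, variant = "simplified")
  expect_equal(b$ic, log2(50000 / 10500), tolerance = 1e-12)
  expect_equal(b$ic, 2.251539, tolerance = 1e-6)
  expect_lt(b$ic025, b$ic)
  # exact independence at large N: IC -> 0 for both variants
  expect_equal(bcpnn_ic(100, 9900, 9900, 980100)$ic, 0, tolerance = 1e-12)
  expect_equal(
    bcpnn_ic(100, 9900, 9900, 980100, variant = "bate")$ic, 0,
    tolerance = 0.02
  )
  # a single report in a huge database: shrinkage dominates, IC025 < 0
  bb <- bcpnn_ic(1, 9, 9, 1e6 - 19, variant = "bate")
  expect_lt(bb$ic025, 0)
  # zero margin errors
  expect_error(bcpnn_ic(0, 0, 5, 100), "margin")
})

test_that("closed-form EBGM matches direct arithmetic", {
  e <- mgps_ebgm(5, 95, 100, 9800)
  expect_equal(e$ebgm, 50000 / 10500, tolerance = 1e-12)
  expect_equal(e$ebgm, 4.761905, tolerance = 1e-6)
  expect_equal(
    e$ebgm05,
    exp(log(50000 / 10500) - 1.645 * sqrt(1 / 5 + 1 / 95 + 1 / 100 + 1 / 9800)),
    tolerance = 1e-12
  )
  # every pair at its expected count: EBGM ~ 1 throughout
  ind <- mgps_ebgm(c(10, 20, 40), c(90, 180, 360), c(90, 180, 360), c(810, 1620, 3240))
  expect_equal(ind$ebgm, rep(1, 3), tolerance = 1e-12)
})

test_that("EM fit recovers a known gamma-Poisson mixture within 15%", {
  set.seed(101)
  n <- 5000
  truth <- c(alpha1 = 2, beta1 = 2, alpha2 = 3, beta2 = 0.3, P = 0.7)
  comp2 <- stats::runif(n) >= truth[["P"]]
  lam <- ifelse(!comp2,
    stats::rgamma(n, truth[["alpha1"]], rate = truth[["beta1"]]),
    stats::rgamma(n, truth[["alpha2"]], rate = truth[["beta2"]])
  )
  E <- stats::runif(n, 1, 50)
  a <- stats::rpois(n, lam * E)
  # embed the (a, E) pairs in 2x2 tables with matching expectations,
  # margins wide enough that no cell can go negative
  N <- 1e8
  L1 <- a + 1000
  L2 <- round(E * N / L1)
  b <- L1 - a
  c <- L2 - a
  d <- N - L1 - L2 + a
  fit <- mgps_ebgm(a, b, c, d, variant = "em")
  est <- attr(fit, "mixture")
  expect_true(all(abs(est - truth) / truth < 0.15))
  expect_true(all(fit$ebgm05 <= fit$ebgm + 1e-12))
  expect_true(all(fit$ebgm > 0))
})

test_that("disproportionality metrics increase in a with margins fixed", {
  n_drug <- 100
  n_event <- 120
  N <- 10000
  a <- 2:30
  b <- n_drug - a
  c <- n_event - a
  d <- N - n_drug - c
  expect_true(all(diff(ror(a, b, c, d)$ror) > 0))
  expect_true(all(diff(prr_chi2(a, b, c, d)$prr) > 0))
  expect_true(all(diff(bcpnn_ic(a, b, c, d)$ic) > 0))
  expect_true(all(diff(mgps_ebgm(a, b, c, d)$ebgm) > 0))
})

test_that("the combined rule is the conjunction of the four criteria", {
  base <- tibble::tibble(
    a = 10, ror_ci_low = 1.5, prr = 3, chi2 = 10, ic025 = 0.5, ebgm05 = 2.5
  )
  expect_true(combined_signal(base)$combined_positive)
  for (col in c("ror_ci_low", "prr", "chi2", "ic025", "ebgm05")) {
    broke <- base
    broke[[col]] <- c(ror_ci_low = 0.9, prr = 1.5, chi2 = 3, ic025 = -0.1, ebgm05 = 1.9)[[col]]
    expect_false(combined_signal(broke)$combined_positive)
  }
  # too few reports fails the count criteria even with strong ratios
  few <- base
  few$a <- 2
  flags <- combined_signal(few)
  expect_false(flags$flag_ror)
  expect_false(flags$flag_prr)
})

test_that("an injected association is detected by all four criteria", {
  sc <- shared_cohort()
  sig <- compute_signals(sc$dataset)
  injected <- sc$cfg$drugs$ingredient[sc$cfg$drugs$rr > 1]
  hit <- sig[sig$drug %in% injected, ]
  expect_true(all(hit$a >= 20))
  expect_true(all(hit$combined_positive))
  # contingency marginals conserve the dataset totals
  tabs <- contingency_tables(sc$dataset)
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == tabs$N))
  expect_true(all(tabs$a + tabs$c == length(sc$dataset$event_positive)))
  # and equal the generator ground truth exactly
  truth <- sc$gen$truth$counts
  m <- dplyr::inner_join(tabs, truth, by = "drug", suffix = c("", ".t"))
  expect_equal(nrow(m), nrow(tabs))
  expect_equal(m$a, m$a.t)
  expect_equal(m$b, m$b.t)
  expect_equal(m$c, m$c.t)
  expect_equal(m$d, m$d.t)
})

test_that("risk stratification reproduces the floor-boundary worked examples", {
  mk <- function(n) {
    tibble::tibble(
      drug = sprintf("d%04d", seq_len(n)),
      ror = rev(seq_len(n)) + 0.5, a = rep(10L, n)
    )
  }
  expect_equal(
    as.vector(table(stratify_risk(mk(135))$risk_level)),
    c(6L, 21L, 40L, 68L)
  )
  expect_equal(
    as.vector(table(stratify_risk(mk(100))$risk_level)),
    c(5L, 15L, 30L, 50L)
  )
  expect_equal(
    as.vector(table(stratify_risk(mk(3))$risk_level)),
    c(0L, 0L, 1L, 2L)
  )
  expect_equal(nrow(stratify_risk(mk(0))), 0L)
})

test_that("stratification partitions the drugs contiguously by ROR rank", {
  set.seed(31)
  for (n in c(1, 2, 7, 19, 135, 200)) {
    s <- tibble::tibble(
      drug = sprintf("d%04d", seq_len(n)),
      ror = stats::rlnorm(n, 1, 1), a = sample(3:50, n, replace = TRUE)
    )
    out <- stratify_risk(s)
    expect_equal(nrow(out), n)
    expect_false(is.unsorted(match(out$risk_level, c("A", "B", "C", "D"))))
    expect_false(is.unsorted(-out$ror))
    sizes <- as.vector(table(out$risk_level))
    expect_equal(sum(sizes), n)
    expect_equal(sizes[1], floor(0.05 * n))
    expect_equal(sizes[1] + sizes[2], floor(0.20 * n))
    expect_equal(sizes[1] + sizes[2] + sizes[3], floor(0.50 * n))
  }
})

test_that("ROR ties in stratification break by report count then drug id", {
  s <- tibble::tibble(
    drug = c("zeta", "alpha", "beta"),
    ror = c(2, 2, 2),
    a = c(5L, 9L, 5L)
  )
  out <- stratify_risk(s)
  expect_equal(out$drug, c("alpha", "beta", "zeta"))
})
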