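test_that("time-to-onset follows the half-day convention with exclusions", {
  tto <- compute_tto(
    parse_date(c("20200101", "20200105", "20200110", "202001", "20200110", "")),
    parse_date(c("20200110", "20200105", "20200101", "20200110", "202002", "20200110"))
  )
  expect_equal(tto$tto_days[1], 9.5) # nine whole days + 0.5
  expect_equal(tto$tto_days[2], 0.5) # same-day onset stays positive
  expect_equal(tto$exclusion_reason[3], "negative_or_zero") # event precedes start
  expect_equal(tto$exclusion_reason[4], "partial_date")
  expect_equal(tto$exclusion_reason[5], "partial_date")
  expect_equal(tto$exclusion_reason[6], "missing_date")
  expect_equal(tto$included, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("exclusion bookkeeping conserves the record count", {
  sc <- shared_cohort()
  tto <- extract_tto(sc$dataset)
  expect_equal(nrow(tto), length(sc$dataset$event_positive))
  expect_equal(sum(tto$included) + sum(!tto$included), nrow(tto))
  expect_true(all(tto$tto_days[tto$included] > 0))
  # included records carry the generator's ground-truth onset exactly
  truth <- sc$gen$truth$cases
  m <- dplyr::inner_join(tto, truth, by = c(drug = "drug", primaryid = "primaryid"))
  inc <- m[m$included, ]
  expect_gt(nrow(inc), 0)
  expect_equal(inc$tto_days.x, inc$tto_days.y)
})

test_that("the Weibull MLE matches a grid-search oracle", {
  t <- c(1, 2, 3, 4, 5, 8, 13, 21, 34, 55)
  fit <- fit_weibull(t, min_n = 10)
  # oracle: profile log-likelihood maximized over a shape grid
  betas <- seq(0.05, 10, by = 1e-3)
  ll <- vapply(betas, function(b) {
    a <- mean(t^b)^(1 / b)
    sum(stats::dweibull(t, shape = b, scale = a, log = TRUE))
  }, numeric(1))
  best <- betas[which.max(ll)]
  expect_equal(round(fit$beta, 2), round(best, 2))
  a_best <- mean(t^best)^(1 / best)
  expect_equal(round(fit$alpha, 2), round(a_best, 2))
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
})

test_that("the Weibull MLE agrees with an independent library fit", {
  set.seed(41)
  t <- stats::rweibull(500, shape = 0.8, scale = 50)
  fit <- fit_weibull(t)
  alt <- fitdistrplus::fitdist(t, "weibull")
  # agreement is limited by the library optimizer's own tolerance
  expect_equal(fit$beta, unname(alt$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$alpha, unname(alt$estimate["scale"]), tolerance = 1e-3)
})

test_that("the Weibull fit is deterministic and errors on degenerate input", {
  set.seed(42)
  t <- stats::rweibull(100, 0.7, 80)
  f1 <- fit_weibull(t)
  f2 <- fit_weibull(t)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_error(fit_weibull(t[1:5]), "at least 10")
  expect_error(fit_weibull(rep(3, 20)), "identical")
  expect_error(fit_weibull(c(t, -1)), "positive")
})

test_that("parameter recovery: shape estimates are unbiased with honest CIs", {
  set.seed(43)
  for (true_beta in c(0.5, 1, 2)) {
    est <- numeric(100)
    cover <- logical(100)
    for (r in 1:100) {
      t <- stats::rweibull(1000, shape = true_beta, scale = 100)
      f <- fit_weibull(t)
      est[r] <- f$beta
      cover[r] <- f$beta_ci[1] <= true_beta && true_beta <= f$beta_ci[2]
    }
    expect_lt(abs(mean(est) - true_beta) / true_beta, 0.02)
    expect_gte(mean(cover), 0.90)
    expect_lte(mean(cover), 0.99)
  }
})

test_that("an exponential sample is recognised as shape 1", {
  set.seed(44)
  t <- stats::rexp(5000, rate = 1 / 30)
  f <- fit_weibull(t)
  expect_true(f$beta_ci[1] < 1 && 1 < f$beta_ci[2])
  expect_equal(classify_failure(f), "random")
})

test_that("failure modes classify by the shape CI against 1", {
  mk <- function(beta, lo, hi) {
    structure(
      list(
        alpha = 100, beta = beta, alpha_ci = c(90, 110),
        beta_ci = c(lo, hi), n = 100, loglik = 0
      ),
      class = "weibull_fit"
    )
  }
  expect_equal(classify_failure(mk(0.649, 0.643, 0.656)), "early")
  expect_equal(classify_failure(mk(1.963, 1.220, 2.707)), "wear_out")
  expect_equal(classify_failure(mk(1.05, 0.8, 1.3)), "random")
})

test_that("median and IQR are type-7 quantiles in days", {
  expect_equal(median_iqr(c(1, 2, 3)), c(median = 2, q1 = 1.5, q3 = 2.5))
  expect_equal(median_iqr(4), c(median = 4, q1 = 4, q3 = 4))
  set.seed(45)
  t <- stats::rweibull(101, 0.6, 120)
  # oracle: sort-and-interpolate by hand (type 7: h = (n-1)p + 1)
  s <- sort(t)
  q7 <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  got <- median_iqr(t)
  expect_equal(unname(got), c(q7(0.5), q7(0.25), q7(0.75)))
})

test_that("without censoring the cumulative incidence equals the ECDF", {
  expect_equal(
    cumulative_incidence(list(g = c(1, 2, 3))) |>
      dplyr::filter(time == 2) |>
      dplyr::pull(cuminc),
    2 / 3
  )
  set.seed(46)
  groups <- list(
    x = stats::rweibull(200, 0.7, 60),
    y = stats::rweibull(150, 1.4, 30)
  )
  ci <- cumulative_incidence(groups)
  for (g in names(groups)) {
    sub <- ci[ci$group == g, ]
    F_hat <- stats::ecdf(groups[[g]])
    expect_equal(max(abs(sub$cuminc - F_hat(sub$time))), 0, tolerance = 1e-12)
    expect_false(is.unsorted(sub$cuminc))
    expect_equal(max(sub$cuminc), 1)
  }
})

test_that("log-rank comparison behaves at its null and at separation", {
  same <- list(a = c(1, 5, 9, 14), b = c(1, 5, 9, 14))
  res <- logrank_test(same)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # three versus three completely separated: the permutation null has
  # only choose(6,3) = 20 labelings, so its smallest attainable p is
  # 2/20; the asymptotic p agrees in rejecting at 5%
  sep <- list(early = c(1, 2, 3), late = c(101, 102, 103))
  res2 <- logrank_test(sep)
  expect_lt(res2$p, 0.05)
  obs <- res2$statistic
  pool <- unlist(sep)
  set.seed(47)
  perm <- replicate(1e4, {
    lab <- sample(rep(c("early", "late"), each = 3))
    logrank_test(data.frame(group = lab, tto_days = pool))$statistic
  })
  p_perm <- mean(perm >= obs - 1e-9)
  expect_lte(p_perm, 0.12) # 2/20 plus Monte-Carlo slack

  # ten versus ten separated groups reach p < 0.01 on both routes
  sep10 <- list(early = 1:10 + 0.5, late = 101:110 + 0.5)
  res3 <- logrank_test(sep10)
  expect_lt(res3$p, 0.01)
  pool10 <- unlist(sep10)
  set.seed(48)
  perm10 <- replicate(2000, {
    lab <- sample(rep(c("early", "late"), each = 10))
    logrank_test(data.frame(group = lab, tto_days = pool10))$statistic
  })
  expect_lt(mean(perm10 >= res3$statistic - 1e-9), 0.01)
  expect_error(logrank_test(list(a = numeric(0), b = 1:3)), "empty")
})

test_that("log-rank type-I error is nominal under a common distribution", {
  set.seed(48)
  rej <- replicate(200, {
    g <- list(
      a = stats::rweibull(30, 0.8, 50),
      b = stats::rweibull(30, 0.8, 50),
      c = stats::rweibull(30, 0.8, 50)
    )
    logrank_test(g)$p < 0.05
  })
  # binomial 95% band around 0.05 with 200 replicates: [0.02, 0.085]
  expect_gte(mean(rej), 0.02 - 1e-9)
  expect_lte(mean(rej), 0.085 + 1e-9)
})

test_that("the onset summary table fits groups above the report minimum", {
  sc <- shared_cohort()
  tto <- extract_tto(sc$dataset)
  overall <- tto_summary(tto, by = NULL)
  expect_equal(overall$n, sum(tto$included))
  expect_false(is.na(overall$beta))
  by_drug <- tto_summary(tto, by = "drug")
  small <- by_drug[by_drug$n <= 10, ]
  expect_true(all(is.na(small$beta)))
  big <- by_drug[by_drug$n > 10, ]
  expect_true(all(!is.na(big$beta)))
  expect_true(all(big$failure_mode %in% c("early", "random", "wear_out")))
})
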