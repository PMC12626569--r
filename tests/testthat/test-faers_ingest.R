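test_that("partial dates parse by format and calendar validity", {
  pd <- parse_date(c(
    "20200110", "202013", "2019", "", "20200230", "20200229",
    "20190229", "1234567", "abc", "202006"
  ))
  expect_equal(pd$precision, c(
    "day", "invalid", "year", "invalid", "invalid", "day",
    "invalid", "invalid", "invalid", "month"
  ))
  expect_equal(pd$year[1], 2020)
  expect_equal(pd$month[1], 1)
  expect_equal(pd$day[1], 10)
  expect_equal(pd$year[3], 2019)
  expect_true(is.na(pd$month[3]))
  # leap-year Feb 29 valid in 2020, not in 2019
  expect_equal(pd$precision[6], "day")
  expect_equal(pd$precision[7], "invalid")
})

test_that("partial date keys order year < month < day precision dates", {
  k <- partial_date_key(c("2020", "202001", "20200101", "20200102", "bad"))
  expect_true(all(diff(k[1:4]) > 0))
  expect_true(is.na(k[5]))
})

test_that("deduplication keeps latest FDA_DT, then highest PRIMARYID", {
  # later date outranks larger id
  demo <- tibble::tibble(
    CASEID = c("1", "1"),
    PRIMARYID = c("10", "9"),
    FDA_DT = c("20200101", "20200301")
  )
  expect_equal(deduplicate(demo)$PRIMARYID, "9")
  # tie on date: highest id wins
  demo2 <- tibble::tibble(
    CASEID = c("1", "1"),
    PRIMARYID = c("10", "12"),
    FDA_DT = c("20200101", "20200101")
  )
  expect_equal(deduplicate(demo2)$PRIMARYID, "12")
  # numeric, not lexicographic, id comparison
  demo3 <- tibble::tibble(
    CASEID = c("1", "1"),
    PRIMARYID = c("9", "100"),
    FDA_DT = c("20200101", "20200101")
  )
  expect_equal(deduplicate(demo3)$PRIMARYID, "100")
})

test_that("deduplication matches a brute-force group-by oracle and is idempotent", {
  set.seed(11)
  n <- 1000L
  caseids <- as.character(sample(1:700, n - 700, replace = TRUE))
  caseids <- c(as.character(1:700), caseids) # every caseid at least once
  demo <- tibble::tibble(
    CASEID = caseids,
    PRIMARYID = as.character(sample(1e6, n)),
    FDA_DT = format(as.Date("2015-01-01") + sample(0:3000, n, replace = TRUE), "%Y%m%d")
  )
  surv <- deduplicate(demo)
  expect_equal(nrow(surv), 700L)
  expect_setequal(surv$CASEID, unique(demo$CASEID))

  # oracle: per caseid, max by (date, numeric pid) via base R
  oracle <- vapply(split(demo, demo$CASEID), function(g) {
    key <- as.numeric(g$FDA_DT) * 1e7 + as.numeric(g$PRIMARYID)
    g$PRIMARYID[which.max(key)]
  }, character(1))
  expect_setequal(surv$PRIMARYID, unname(oracle))

  # idempotent
  again <- deduplicate(surv)
  expect_equal(sort(again$PRIMARYID), sort(surv$PRIMARYID))
})

test_that("all-unparseable FDA_DT keeps highest PRIMARYID with a warning", {
  demo <- tibble::tibble(
    CASEID = c("1", "1"),
    PRIMARYID = c("5", "7"),
    FDA_DT = c("", "bad")
  )
  expect_warning(out <- deduplicate(demo), "parseable")
  expect_equal(out$PRIMARYID, "7")
})

test_that("reader parses well-formed rows and counts skipped malformed ones", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "PRIMARYID$CASEID$FDA_DT$SEX",
    "101$1$20200101$F",
    "102$2$20200102$M",
    "103$3", # too few fields -> skipped
    "104$4$20200104$"
  ), f)
  tab <- read_faers_table(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_skipped"), 1L)
  expect_equal(tab$SEX, c("F", "M", ""))
})

test_that("missing mandatory column is a hard error naming file and column", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PRIMARYID$FDA_DT", "101$20200101"), f)
  expect_error(read_faers_table(f), "CASEID")
  expect_error(read_faers_table(f), basename(f))
})

test_that("a synthetic quarter round-trips through write and read byte-for-byte", {
  sc <- shared_cohort()
  dir <- withr::local_tempdir()
  paths <- write_quarter(sc$gen$tables, dir, quarter = "24Q1")
  expect_true(all(file.exists(unlist(paths))))
  rt <- read_quarter(paths)
  for (r in c("demo", "drug", "reac", "ther", "outc", "rpsr")) {
    orig <- sc$gen$tables[[r]]
    got <- rt[[r]]
    expect_identical(
      lapply(as.list(got), unname), lapply(as.list(orig), unname),
      info = r
    )
  }
  expect_equal(sum(rt$log$n_skipped), 0L)
})

test_that("dedup of generated duplicates restores exactly n_cases survivors", {
  sc <- shared_cohort()
  dd <- apply_dedup(sc$gen$tables)
  expect_equal(nrow(dd$demo), sc$cfg$n_cases)
  expect_gt(nrow(sc$gen$truth$duplicates), 0L)
  # the surviving version of a duplicated case is the later, higher-id one
  dup <- sc$gen$truth$duplicates
  kept <- dd$demo$PRIMARYID[match(dup$caseid, dd$demo$CASEID)]
  expect_true(all(kept == dup$primaryid_duplicate))
})
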