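test_that("growth rates reproduce the reported trial arithmetic", {
  expect_equal(growthRate(37, 37), 0)
  expect_equal(growthRate(41.295, 49.615), 20.1)
  expect_equal(growthRate(22.95, 45.75), 99.3)
  expect_error(growthRate(0, 5), "pre")
})

test_that("growth rate inverts percentage changes for any p > -100", {
  for (p in c(-99.9, -50, -0.1, 0, 0.1, 7.3, 250)) {
    x <- 12.34
    expect_equal(growthRate(x, x * (1 + p / 100)), round(p, 1),
                 tolerance = 0.051)
  }
})

test_that("injury rate is bounded and additive over disjoint cohorts", {
  expect_equal(injuryRate(0, 20), 0)
  expect_equal(injuryRate(3, 20), 15.0)
  expect_equal(injuryRate(9, 20), 45.0)
  ## weighted recombination of disjoint cohorts
  r1 <- injuryRate(3, 20); r2 <- injuryRate(5, 30)
  expect_equal((r1 * 20 + r2 * 30) / 50, injuryRate(8, 50),
               tolerance = 0.05)
  expect_error(injuryRate(5, 4), "injured")
  expect_error(injuryRate(1, 0), "total")
})

test_that("percent change reproduces the ablation-table cells", {
  expect_equal(percentChange(0.99, 0.78), -21.2)
  expect_equal(percentChange(52.7, 94.3), 78.9)
  expect_equal(percentChange(12, 5), -58.3)
  expect_error(percentChange(0, 5), "nonzero")
})

## long-format fixture: nPer subjects per group, week0 and week12
makeRecords <- function(iv0, iv12, cv0, cv12, injI = 0, injC = 0) {
  n <- length(iv0)
  rows <- list()
  add <- function(i, grp, tp, v, reps, inj) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = sprintf("%s%02d", substr(grp, 1, 1), i), group = grp,
      timepoint = tp, vo2max = v, reps = reps, injured = inj)
  }
  for (i in seq_len(n)) {
    add(i, "intervention", "week0", iv0[i], round(iv0[i] / 2), FALSE)
    add(i, "intervention", "week12", iv12[i], round(iv12[i] / 2),
        i <= injI)
    add(i, "control", "week0", cv0[i], round(cv0[i] / 2), FALSE)
    add(i, "control", "week12", cv12[i], round(cv12[i] / 2), i <= injC)
  }
  do.call(rbind, rows)
}

test_that("identical groups give zero mean difference and zero effect size", {
  v0 <- c(40, 41, 42, 43); v12 <- c(44, 45, 46, 47)
  rec <- makeRecords(v0, v12, v0, v12)
  gc <- groupCompare(rec, "vo2max")
  expect_equal(gc$between_week12$meanDiff, 0)
  expect_equal(gc$between_week12$d, 0)
  expect_equal(gc$between_change$meanDiff, 0)
})

test_that("the between-group mean difference matches the reported endurance gap", {
  ## week-12 endurance means 45.75 vs 30.2 -> mean difference 15.55
  rec <- makeRecords(iv0 = c(22, 23, 23, 24),
                     iv12 = c(44.75, 46.75, 45.25, 46.25),
                     cv0 = c(22, 22, 23, 22),
                     cv12 = c(29.2, 31.2, 29.7, 30.7))
  rec$reps <- rec$vo2max   # score the same values as the reps outcome
  gc <- groupCompare(rec, "reps")
  expect_equal(gc$between_week12$meanDiff, 15.55, tolerance = 1e-9)
  expect_true(gc$between_week12$ci[1] < 15.55 &
                gc$between_week12$ci[2] > 15.55)
})

test_that("the paired t statistic matches the closed-form recomputation", {
  iv0 <- c(40.1, 42.3, 39.8, 41.6); iv12 <- c(46.2, 47.9, 44.1, 48.3)
  rec <- makeRecords(iv0, iv12, c(40, 41, 42, 40), c(41, 42, 42.5, 41.2))
  gc <- groupCompare(rec, "vo2max")
  w <- gc$within[[1]]
  d <- iv12 - iv0
  tHand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_identical(w$test$method, "paired-t")
  expect_equal(w$test$statistic, tHand, tolerance = 1e-9)
  ## Cohen's d pooled-SD closed form
  x <- iv12; y <- c(41, 42, 42.5, 41.2)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(gc$between_week12$d, (mean(x) - mean(y)) / sp,
               tolerance = 1e-9)
})

test_that("injury comparison selects chi-square or the exact fallback correctly", {
  v0 <- 40 + seq(0, 1.9, length.out = 20) * rep(c(1, -1), 10)
  rec <- makeRecords(rep(v0, length.out = 20) + rnorm(20, 0, 0.3),
                     40 + rnorm(20), 40 + rnorm(20), 41 + rnorm(20),
                     injI = 3, injC = 9)
  gc <- groupCompare(rec, "injured")
  expect_equal(gc$groups[[1]]$rate, 15.0)
  expect_equal(gc$groups[[2]]$rate, 45.0)
  expect_true(gc$test$method %in% c("chi-square", "fisher"))
  expect_true(gc$test$p >= 0 && gc$test$p <= 1)
})

test_that("the trial report equals direct metric recomputation and lists missing subjects", {
  rec <- makeRecords(c(40, 41, 42, 43), c(46, 47, 49, 50),
                     c(40, 41, 42, 43), c(41, 42, 43, 44), injI = 1)
  rep <- trialReport(rec)
  s <- rep$summary$intervention
  expect_equal(s$vo2max_growth,
               growthRate(mean(c(40, 41, 42, 43)),
                          mean(c(46, 47, 49, 50))))
  expect_equal(s$injury_rate, injuryRate(1, 4))
  expect_length(rep$incomplete, 0)
  ## JSON round trip preserves the summary
  js <- jsonlite::fromJSON(jsonlite::toJSON(rep$summary, auto_unbox = TRUE))
  expect_equal(js$intervention$vo2max_growth, s$vo2max_growth)
  ## a subject missing week12 is listed and excluded
  rec2 <- rec[!(rec$subject == "i01" & rec$timepoint == "week12"), ]
  rep2 <- trialReport(rec2)
  expect_equal(rep2$incomplete, "i01")
  expect_equal(rep2$summary$intervention$n, 3)
})

test_that("a null-effect fixture reports near-zero growth everywhere", {
  v <- c(40, 41, 42, 43)
  rec <- makeRecords(v, v + 0.001, v, v + 0.001)
  rep <- trialReport(rec)
  expect_equal(rep$summary$intervention$vo2max_growth, 0)
  expect_equal(rep$summary$control$vo2max_growth, 0)
})
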