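# Period assignment, monthly rates, proportion tests, Cohen's h, SESOI.

mk_class <- function(flagged, rejected = rep(FALSE, length(flagged))) {
  structure(list(method = "test", flagged = flagged, rejected = rejected,
                 n_flagged = sum(flagged & !rejected),
                 n_classified = sum(!rejected),
                 n_rejected = sum(rejected),
                 rate = sum(flagged & !rejected) / sum(!rejected)),
            class = "lapse_classification")
}

test_that("assign_period maps months to labels, exclusions and scope", {
  cfg <- period_config()
  ts <- as.POSIXct(c("2020-04-15", "2020-03-10", "2020-02-29", "2019-01-01",
                     "2020-05-31 23:59:59", "2020-06-01 00:00:00",
                     "2023-01-01", "2018-12-31"), tz = "UTC")
  expect_equal(assign_period(ts, cfg),
               c("peak_covid", "excluded", "pre_covid", "pre_covid",
                 "peak_covid", "post_peak", "out_of_scope", "out_of_scope"))
  # month strings are accepted directly
  expect_equal(assign_period("2022-12", cfg), "post_peak")
})

test_that("period_config rejects overlapping periods", {
  expect_error(period_config(periods = list(a = c("2019-01", "2019-06"),
                                            b = c("2019-06", "2019-12"))),
               "overlap")
  # overlap resolved via exclusions is fine
  cfg <- period_config(periods = list(a = c("2019-01", "2019-06"),
                                      b = c("2019-07", "2019-12")),
                       excluded = character())
  expect_equal(assign_period("2019-07", cfg), "b")
})

test_that("seasonal_config builds one period per year", {
  cfg <- seasonal_config()
  expect_length(cfg$periods, 4L)
  expect_equal(assign_period("2020-04", cfg), assign_period("2020-05", cfg))
  expect_equal(assign_period("2021-05", cfg), "Apr_May_2021")
  expect_equal(assign_period("2021-06", cfg), "out_of_scope")
})

test_that("monthly unweighted mean ignores volume", {
  rec <- rbind(
    mk_records(rep(10, 100), offset = seq_len(100),
               start = as.POSIXct("2019-03-01", tz = "UTC")),
    mk_records(rep(10, 10), offset = seq_len(10),
               start = as.POSIXct("2019-04-01", tz = "UTC")))
  flags <- c(rep(c(TRUE, FALSE), c(1, 99)),   # March: rate 0.01
             rep(c(TRUE, FALSE), c(3, 7)))    # April: rate 0.30
  mr <- monthly_rates(rec, mk_class(flags))
  expect_equal(mr$monthly$rate, c(0.01, 0.30))
  expect_equal(mr$mean_monthly_rate, 0.155)   # not the pooled 4/110
  # single month: unweighted mean = pooled rate
  one <- monthly_rates(rec[1:100], mk_class(flags[1:100]))
  expect_equal(one$mean_monthly_rate, 0.01)
  # rejected records are excluded from both counts
  rej <- monthly_rates(rec, mk_class(flags, rejected = c(rep(TRUE, 100),
                                                         rep(FALSE, 10))))
  expect_equal(rej$monthly$total, 10L)
})

test_that("equal_proportions_test matches hand Pearson and prop.test", {
  # identical proportions -> statistic 0
  expect_equal(equal_proportions_test(c(10, 20), c(100, 200))$chi2, 0)
  # hand-computed 2x2 Pearson without correction: 8/3
  got <- equal_proportions_test(c(30, 20), c(100, 100))
  expect_equal(got$chi2, 8 / 3)
  expect_equal(got$df, 1L)
  # continuity correction only applies when requested and k = 2
  expect_lt(equal_proportions_test(c(30, 20), c(100, 100), correct = TRUE)$chi2,
            8 / 3)
  # degenerate pooled proportion warns and returns 0
  expect_warning(z <- equal_proportions_test(c(0, 0), c(50, 50)))
  expect_equal(z$chi2, 0)
})

test_that("equal_proportions_test equals the textbook Pearson on random
           k x 2 tables", {
  set.seed(14)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    total <- sample(50:10000, k, replace = TRUE)
    p <- runif(1, 0.02, 0.5)
    flagged <- pmin(rbinom(k, total, p), total)
    if (sum(flagged) == 0) next
    got <- equal_proportions_test(flagged, total)
    expect_equal(got$chi2, o_pearson(flagged, total))
    expect_equal(got$df, k - 1L)
  }
})

test_that("cohens_h is exact on direct evaluation and antisymmetric", {
  expect_equal(cohens_h(0.3, 0.3), 0)
  expect_equal(cohens_h(0.25, 0.16), 2 * (asin(0.5) - asin(0.4)))
  set.seed(15)
  p <- runif(40)
  q <- runif(40)
  expect_equal(cohens_h(p, q), -cohens_h(q, p))
  expect_true(all(abs(cohens_h(p, q)) <= pi))
  expect_equal(cohens_h(1, 0), pi)
})

test_that("sesoi_verdict compares |h| inclusively", {
  expect_equal(sesoi_verdict(0.0007, 0.5), "below_sesoi")
  expect_equal(sesoi_verdict(-0.6, 0.5), "at_or_above_sesoi")
  expect_equal(sesoi_verdict(0.3, 0.3), "at_or_above_sesoi")
})

test_that("combine_rates adds disjoint event-class rates", {
  expect_equal(combine_rates(0.02855, 0.00351), 0.03206)
  expect_equal(combine_rates(0, 0), 0)
  expect_error(combine_rates(0.9, 0.2))
})

test_that("period_report pools counts consistently with raw flags", {
  log <- simulate_eventlog(eventlog_config(n_learners = 40, seed = 19))
  rec <- log$records
  cls <- classify_interruptions(rec, duration_thresholds(stratum_stats(rec)))
  rep_ <- period_report(rec, cls)
  expect_equal(sum(rep_$periods$interruptions) +
                 sum(cls$flagged[assign_period(rec$start_time) %in%
                                   c("excluded", "out_of_scope")]),
               cls$n_flagged)
  # pooled period rate equals flags/interactions recomputed from raw flags
  per <- assign_period(rec$start_time)
  for (p in rep_$periods$period) {
    in_p <- per == p & !cls$rejected
    expect_equal(rep_$periods[period == p, rate],
                 sum(cls$flagged[in_p]) / sum(in_p))
  }
  expect_equal(rep_$test$df, nrow(rep_$periods) - 1L)
  expect_equal(nrow(rep_$pairwise), choose(nrow(rep_$periods), 2))
  # SESOI routing: named comparison gets 0.5, others the 0.3 default
  pw <- rep_$pairwise
  expect_equal(pw[p1 == "pre_covid" & p2 == "peak_covid", sesoi], 0.5)
  expect_equal(pw[p1 == "pre_covid" & p2 == "post_peak", sesoi], 0.3)
})

test_that("a step change in injection rate is recovered as Cohen's h", {
  # two one-month cohorts with different injection rates; the estimated h
  # converges to 2 asin(sqrt(pi1)) - 2 asin(sqrt(pi2))
  mk_cohort <- function(pi0, month, seed) {
    cfg <- eventlog_config(
      n_learners = 80, n_modules = 2, interruption_prob = pi0,
      pause_sampler = function(n) rlnorm(n, log(1e5), 0.2),
      long_break_prob = 0, calendar_start = month, calendar_end = month,
      seed = seed)
    simulate_eventlog(cfg)$records
  }
  rec <- rbind(mk_cohort(0.02, "2019-06", 101), mk_cohort(0.10, "2020-04", 102))
  cls <- classify_interruptions(rec, duration_thresholds(stratum_stats(rec)))
  rep_ <- period_report(rec, cls)
  h_est <- rep_$pairwise[p1 == "pre_covid" & p2 == "peak_covid", h]
  h_true <- cohens_h(0.02, 0.10)
  n_eff <- min(rep_$periods$interactions)
  expect_lt(abs(h_est - h_true), 6 * 1 / sqrt(n_eff) + 0.02)
  expect_lt(abs(h_est - h_true), 0.1)
})
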