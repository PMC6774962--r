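test_that("damage reduction follows the relative-risk formula", {
  expect_equal(damage_reduction(0, 100, 5, 100), 100)   # complete protection
  expect_equal(damage_reduction(3, 50, 6, 100), 0)      # equal rates, RR = 1
  expect_equal(damage_reduction(4, 100, 2, 100), -100)  # damage doubled
  expect_true(is.na(damage_reduction(1, 50, 0, 50)))    # RR undefined at B = 0
  expect_error(damage_reduction(1, 0, 2, 10), "positive")
  expect_error(damage_reduction(-1, 10, 2, 10), "non-negative")
  # vectorized, capped at 100 above, unbounded below
  r <- damage_reduction(c(0, 5, 50), 100, c(5, 0, 5), 100)
  expect_equal(r, c(100, NA, -900))
})

test_that("incremental trend pools counts and exposures cumulatively", {
  cs <- make_case(A = c(0, 1), B = c(2, 1), Nt = 1, Nc = 1,
                  design = "before_after")
  tr <- incremental_trend(cs)
  expect_s3_class(tr, "trend_line")
  expect_equal(tr$points$reduction_pct, c(100, 100 * (1 - (1 / 2) / (3 / 2))))
  expect_equal(tr$n_defined, 2)

  # zero treatment damage throughout: every defined point is 100
  cs <- make_case(A = rep(0L, 5), B = c(0, 2, 0, 1, 3))
  tr <- incremental_trend(cs)
  expect_true(all(tr$points$reduction_pct == 100))

  # leading control-free intervals are excluded; the trend starts at the
  # first time with cumulative control damage
  cs <- make_case(A = c(1, 0, 2, 1), B = c(0, 0, 3, 1))
  tr <- incremental_trend(cs)
  expect_equal(tr$points$time, c(3, 4))
  expect_equal(nrow(tr$full), 4)
  expect_true(all(is.na(tr$full$reduction_pct[1:2])))
})

test_that("interval exclusion rule drops B = 0 intervals from the sums", {
  cs <- make_case(A = c(5, 1, 2), B = c(0, 3, 1))
  cum <- incremental_trend(cs, exclusion = "cumulative")
  itv <- incremental_trend(cs, exclusion = "interval")
  # cumulative: first interval's A = 5 stays in the pooled numerator
  expect_equal(cum$points$time, c(2, 3))
  expect_equal(cum$points$cum_A, c(6, 8))
  # interval: the B = 0 interval vanishes entirely
  expect_equal(itv$points$time, c(2, 3))
  expect_equal(itv$points$cum_A, c(1, 3))
})

test_that("trend invariants hold: monotone totals, pooled endpoint, scale invariance", {
  set.seed(21)
  for (i in 1:20) {
    cs <- random_case(sprintf("r%d", i))
    tr <- incremental_trend(cs)
    p <- tr$full
    expect_true(all(diff(p$cum_A) >= 0) && all(diff(p$cum_B) >= 0))
    expect_true(all(diff(p$cum_Nt) > 0) && all(diff(p$cum_Nc) > 0))
    # cumulative construction makes the last point the whole-study estimate
    iv <- cs$intervals
    pooled <- damage_reduction(sum(iv$A), sum(iv$Nt), sum(iv$B), sum(iv$Nc))
    if (tr$n_defined > 0 && max(tr$points$time) == nrow(iv))
      expect_equal(tr$points$reduction_pct[tr$n_defined], pooled)
  }
  # before-after: common exposure rescaling leaves every point unchanged
  cs1 <- make_case(A = c(1, 0, 2), B = c(2, 1, 1), Nt = 50, Nc = 50,
                   design = "before_after")
  cs2 <- make_case(A = c(1, 0, 2), B = c(2, 1, 1), Nt = 500, Nc = 500,
                   design = "before_after")
  expect_equal(incremental_trend(cs1)$points$reduction_pct,
               incremental_trend(cs2)$points$reduction_pct)
})

test_that("trend equals the brute-force summation oracle", {
  set.seed(31)
  for (i in 1:50) {
    cs <- random_case(sprintf("o%d", i))
    tr <- incremental_trend(cs)
    or <- oracle_trend(cs)
    expect_equal(tr$points$time, or$time)
    expect_equal(tr$points$reduction_pct, or$reduction_pct, tolerance = 1e-12)
  }
})

test_that("percentages mode averages reported rates with unit weights", {
  iv <- data.frame(period_index = 1:3,
                   rate_treatment_pct = c(0, 10, 20),
                   rate_control_pct = c(20, 20, 50))
  cs <- case_study("pct", iv, mode = "percentages")
  tr <- incremental_trend(cs)
  # point 2: mean treatment rate 5, mean control rate 20 -> RR = 0.25
  expect_equal(tr$points$reduction_pct[2], 75)
  expect_equal(tr$points$reduction_pct[3],
               100 * (1 - mean(iv$rate_treatment_pct) / mean(iv$rate_control_pct)))
})

test_that("trend data frame export carries case metadata", {
  cs <- make_case(A = c(1, 0, 2, 1), B = c(0, 0, 3, 1))
  df <- as.data.frame(incremental_trend(cs), full_grid = TRUE)
  expect_equal(nrow(df), 4)
  expect_true(all(c("case_id", "time", "rr", "reduction_pct", "time_unit")
                  %in% names(df)))
})
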