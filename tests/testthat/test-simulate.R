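test_that("efficacy curves follow the scenario formulas", {
  cfg <- scenario_config("least", e_max = 1)
  expect_equal(efficacy_curve(cfg, c(1, 10, 24)), rep(1, 3))

  cfg <- scenario_config("slow", e_max = 1, tau = 12, decline_rate = 0.1)
  expect_equal(efficacy_curve(cfg, 12), 1)
  expect_equal(efficacy_curve(cfg, 17), 0.5)

  cfg <- scenario_config("fast", e_max = 0.9, tau = 3)
  expect_equal(efficacy_curve(cfg, 3), 0.9 * exp(-1))

  cfg <- scenario_config("counterproductive", e_max = 0.8, n_periods = 24)
  expect_equal(efficacy_curve(cfg, 24), -0.8)
  expect_equal(efficacy_curve(cfg, 12), -0.4)

  expect_error(efficacy_curve(cfg, 0), "1..n_periods")
  expect_error(efficacy_curve(cfg, 25), "1..n_periods")
  expect_error(scenario_config("sideways"))
})

test_that("efficacy curves are monotone as the scenarios require", {
  t <- 1:24
  slow <- efficacy_curve(scenario_config("slow"), t)
  expect_true(all(diff(slow[12:24]) <= 0))
  expect_true(all(diff(efficacy_curve(scenario_config("fast"), t)) <= 0))
  expect_true(all(diff(efficacy_curve(
    scenario_config("counterproductive"), t)) <= 0))
})

test_that("perfect constant efficacy yields zero treatment damage and a flat trend", {
  sim <- simulate_case(scenario_config("least", e_max = 1, seed = 5))
  expect_true(all(sim$case$intervals$A == 0))
  tr <- incremental_trend(sim$case)
  expect_true(all(tr$points$reduction_pct == 100))
})

test_that("identical seeds reproduce identical cases; RNG state is untouched", {
  cfg <- scenario_config("slow", seed = 99)
  set.seed(1234)
  s1 <- simulate_case(cfg)
  r_after <- runif(1)
  set.seed(1234)
  s2 <- simulate_case(cfg)
  expect_identical(s1$case$intervals, s2$case$intervals)
  expect_equal(runif(1), r_after)  # global RNG stream unaffected
})

test_that("control counts match the binomial expectation", {
  # 24 periods x Binomial(100, 0.05): expected cumulative control damage 120
  n_rep <- 500
  cum_b <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_case(scenario_config("least", p0 = 0.05, seed = 20000 + i))
    sum(sim$case$intervals$B)
  }, numeric(1))
  se <- sd(cum_b) / sqrt(n_rep)
  expect_lt(abs(mean(cum_b) - 120), 3 * se)
})

test_that("the noise-free expected trend is the large-exposure limit", {
  cfg_big <- scenario_config("slow", Nt = 1e4, Nc = 1e4, seed = 7)
  sim <- simulate_case(cfg_big)
  tr_mc <- incremental_trend(sim$case)
  tr_exp <- expected_trend(cfg_big)
  shared <- intersect(tr_mc$points$time, tr_exp$points$time)
  dev <- abs(tr_mc$points$reduction_pct[match(shared, tr_mc$points$time)] -
               tr_exp$points$reduction_pct[match(shared, tr_exp$points$time)])
  expect_lte(max(dev), 2)
})

test_that("simulated suites are deterministic and carry ground truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_suite(1, base_seed = 42, dir = d1)
  s2 <- simulate_suite(1, base_seed = 42, dir = d2)
  expect_length(s1$cases, 4)
  expect_setequal(s1$truth$scenario,
                  c("least", "slow", "fast", "counterproductive"))
  expect_identical(readLines(file.path(d1, "cases.csv")),
                   readLines(file.path(d2, "cases.csv")))
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  expect_true("psi_true_of_trend" %in% names(s1$truth))
  # slow scenario has a well-defined noise-free threshold after the plateau
  psi_slow <- s1$truth$psi_true_of_trend[s1$truth$scenario == "slow"]
  expect_gt(psi_slow, s1$truth$tau[s1$truth$scenario == "slow"])
  expect_error(simulate_suite(0), "at least 1")
})

test_that("config invariants are enforced", {
  expect_error(scenario_config("least", p0 = 0), "p0 > 0")
  expect_error(scenario_config("least", e_max = 1.2), "e_max <= 1")
  expect_error(scenario_config("least", n_periods = 1), "n_periods >= 2")
})
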