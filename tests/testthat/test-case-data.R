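test_that("case construction enforces the interval invariants", {
  expect_s3_class(make_case(A = c(0, 1), B = c(2, 1)), "case_study")
  # a single interval is not a trend
  expect_error(make_case(A = 0, B = 2), "at least two")
  # before-after requires equal exposures on every interval
  expect_error(make_case(A = c(0, 1), B = c(2, 1), Nt = 100, Nc = 50,
                         design = "before_after"), "Nt = Nc")
  expect_s3_class(make_case(A = c(0, 1), B = c(2, 1), Nt = 80, Nc = 80,
                            design = "before_after"), "case_study")
  expect_error(make_case(A = c(0, -1), B = c(2, 1)), "negative")
  expect_error(make_case(A = c(0, 1.5), B = c(2, 1)), "integers")
  expect_error(make_case(A = c(0, 1), B = c(2, 1), Nt = 0), "positive")
  expect_error(
    case_study("gap", data.frame(period_index = c(1, 3), A = 0:1,
                                 Nt = 1, B = 1:2, Nc = 1)),
    "consecutive")
})

test_that("percentages mode validates rate domains", {
  iv <- data.frame(period_index = 1:2, rate_treatment_pct = c(0, 150),
                   rate_control_pct = c(10, 20))
  expect_s3_class(case_study("p1", iv, mode = "percentages"), "case_study")
  iv$rate_control_pct <- c(10, 120)  # control rate cannot exceed 100
  expect_error(case_study("p2", iv, mode = "percentages"), "\\[0, 100\\]")
  iv$rate_control_pct <- c(10, 20)
  iv$rate_treatment_pct <- c(-5, 10)
  expect_error(case_study("p3", iv, mode = "percentages"), "non-negative")
})

test_that("write/read round-trips case lists exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  cs <- make_case(A = c(0, 1, 3), B = c(2, 1, 0), Nt = 120.5, Nc = 80)
  write_cases(list(cs), f)
  back <- read_cases(f)
  expect_length(back, 1)
  expect_identical(back[[1]]$case_id, cs$case_id)
  expect_identical(back[[1]]$predators, cs$predators)
  expect_identical(back[[1]]$design, cs$design)
  expect_equal(back[[1]]$intervals$A, cs$intervals$A)
  expect_equal(back[[1]]$intervals$Nt, cs$intervals$Nt)
  expect_equal(back[[1]]$intervals$B, cs$intervals$B)
  expect_equal(back[[1]]$intervals$Nc, cs$intervals$Nc)

  # 26 synthetic cases in, 26 out, field-for-field
  set.seed(11)
  cases <- lapply(sprintf("case_%02d", 1:26), random_case)
  names(cases) <- vapply(cases, `[[`, "", "case_id")
  write_cases(cases, f)
  back <- read_cases(f)
  expect_length(back, 26)
  expect_identical(names(back), names(cases))
  for (id in names(cases)) {
    expect_equal(back[[id]]$intervals[, c("period_index", "A", "Nt", "B", "Nc")],
                 cases[[id]]$intervals[, c("period_index", "A", "Nt", "B", "Nc")])
  }
})

test_that("empty case list writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_cases(list(), f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_length(read_cases(f), 0)
})

test_that("schema and validation errors are informative", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(case_id = "x", period_index = 1, A = 0)
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_cases(f), "missing required columns")

  cs <- make_case(A = c(0, 1), B = c(2, 1))
  write_cases(list(cs), f)
  raw <- utils::read.csv(f)
  raw$A[2] <- -3
  utils::write.csv(raw, f, row.names = FALSE)
  err <- tryCatch(read_cases(f), error = conditionMessage)
  expect_match(err, "c1")       # names the case
  expect_match(err, "rows 3")   # names the offending CSV line
})
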