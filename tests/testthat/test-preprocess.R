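# One shared raw-stream fixture per gap scenario, built in code.
stream_fixture <- function(gap_spec = NULL, days = 7, n = 1, seed = 61) {
  simulate_raw_cgm_stream(tiny_config(n = n, seed = seed), days = days,
                          gap_spec = gap_spec)
}

test_that("quality filters drop the first day and long-gap days only", {
  raw <- stream_fixture()
  qf <- apply_quality_filters(raw$stream)
  days_kept <- unique(as.Date(qf$stream$time, tz = "UTC"))
  expect_length(days_kept, 6) # days 2-7 of a complete 7-day stream
  expect_false(as.Date("2024-03-01") %in% days_kept)
  expect_equal(qf$exclusions$reason, "first_day")

  # 180-min gap: that day excluded
  raw2 <- stream_fixture(list(list(day = 3, start_minute = 600,
                                   duration = 180)))
  qf2 <- apply_quality_filters(raw2$stream)
  expect_length(unique(as.Date(qf2$stream$time, tz = "UTC")), 5)
  expect_true(any(grepl("gap_180", qf2$exclusions$reason)))

  # 120-min gap: the rule is strictly "more than two hours", day retained
  raw3 <- stream_fixture(list(list(day = 4, start_minute = 480,
                                   duration = 120)))
  qf3 <- apply_quality_filters(raw3$stream)
  expect_length(unique(as.Date(qf3$stream$time, tz = "UTC")), 6)
})

test_that("quality filtering is idempotent and warns on short streams", {
  raw <- stream_fixture()
  once <- apply_quality_filters(raw$stream)
  twice <- apply_quality_filters(once$stream)
  expect_identical(once$stream, twice$stream)
  expect_equal(nrow(twice$exclusions), 0)

  short <- raw$stream[as.Date(raw$stream$time, tz = "UTC") ==
                        as.Date("2024-03-01"), ]
  expect_warning(qs <- apply_quality_filters(short), "shorter than 24 h")
  expect_equal(nrow(qs$stream), 0)
})

test_that("window extraction applies the missingness policy exactly", {
  # complete stream: dinners on days 2-6 give complete windows; the day-1
  # dinner loses its data to the first-day rule and the day-7 dinner is
  # truncated by the end of wear, so both fail the 80% rule
  raw <- stream_fixture()
  qf <- apply_quality_filters(raw$stream)
  data <- extract_windows(qf$stream, raw$meals)
  expect_equal(nrow(data$Y), 5)
  expect_true(all(is.finite(data$Y)))
  log <- window_log(data)
  expect_equal(nrow(log), 7)
  expect_equal(sum(log$kept), 5)

  # 45-min gap inside the day-3 dinner window: that window is dropped
  raw2 <- stream_fixture(list(list(day = 3, start_minute = 1290,
                                   duration = 45)))
  qf2 <- apply_quality_filters(raw2$stream)
  data2 <- extract_windows(qf2$stream, raw2$meals)
  expect_equal(nrow(data2$Y), 4)
  log2 <- window_log(data2)
  expect_match(log2$reason[!log2$kept & !is.na(log2$reason)][2], "gap_45")

  # 25-min gap inside a window: interpolated, window retained
  raw3 <- stream_fixture(list(list(day = 3, start_minute = 1290,
                                   duration = 25)))
  qf3 <- apply_quality_filters(raw3$stream)
  data3 <- extract_windows(qf3$stream, raw3$meals)
  expect_equal(nrow(data3$Y), 5)
  expect_true(all(is.finite(data3$Y)))
})

test_that("meals close in time are retained and flagged as overlapping", {
  raw <- stream_fixture()
  qf <- apply_quality_filters(raw$stream)
  extra <- raw$meals[2, ]
  extra$meal_time <- extra$meal_time - 5 * 3600 # 5 h before day-2 dinner
  meals <- dplyr::bind_rows(raw$meals, extra)
  data <- extract_windows(qf$stream, meals)
  log <- window_log(data)
  expect_equal(sum(log$kept), 6)
  expect_gte(sum(log$overlaps), 2)
})

test_that("baseline glucose uses the -5 min sample with the stated tie rule", {
  t0 <- as.POSIXct("2024-03-02 12:00:00", tz = "UTC")
  stream <- tibble::tibble(
    subject_id = "S001",
    time = t0 + c(-9, -6, -4, 0) * 60,
    glucose = c(90, 99, 101, 120)
  )
  # nearest to -5 min: -6 and -4 tie; rule picks the later sample
  expect_equal(baseline_glucose(stream, t0), 101)
  # exact observation at -5 min
  stream2 <- tibble::tibble(subject_id = "S001", time = t0 - 5 * 60,
                            glucose = 101)
  expect_equal(baseline_glucose(stream2, t0), 101)
  # nearest observation outside the +/- 2.5 min tolerance
  stream3 <- tibble::tibble(subject_id = "S001", time = t0 - 9 * 60,
                            glucose = 95)
  expect_true(is.na(baseline_glucose(stream3, t0)))
})

test_that("covariate attachment aligns subject, meal and baseline records", {
  raw <- stream_fixture(n = 2, seed = 62)
  qf <- apply_quality_filters(raw$stream)
  data <- extract_windows(qf$stream, raw$meals)
  subjects <- simulate_subject_table(tiny_config(n = 2, seed = 62))
  cov <- attach_covariates(data, subjects, raw$meals, stream = qf$stream)
  expect_equal(nrow(cov), nrow(data$Y))
  # default design: 10 covariate columns
  design_cols <- c("intercept", "age", "weight", "gender_male", "hba1c",
                   "carbohydrates", "fats", "proteins", "fiber",
                   "initial_glucose")
  expect_true(all(design_cols %in% names(cov)))
  expect_length(design_cols, 10)
  # subject-level fields constant within subject
  for (f in c("age", "weight", "hba1c")) {
    expect_true(all(tapply(cov[[f]], cov$subject_id,
                           function(x) length(unique(x))) == 1))
  }
  # baselines exist on a gap-free stream; breaking one marks the row
  expect_true(all(cov$fosr_ready))
  # unresolvable subject errors
  expect_error(attach_covariates(data, subjects[1, ], raw$meals,
                                 stream = qf$stream),
               "Unresolvable subject")
})

test_that("no snapped value comes from more than half a cadence away", {
  t0 <- as.POSIXct("2024-03-02 12:00:00", tz = "UTC")
  g <- make_grid(0, 10, 5) # targets at 0, 5, 10 min
  # observations at +2 min offsets: within tolerance, values identifiable
  stream <- tibble::tibble(
    subject_id = "S001",
    time = t0 + c(2, 7, 12) * 60,
    glucose = c(101, 102, 103)
  )
  meals <- tibble::tibble(subject_id = "S001", meal_time = t0,
                          meal_label = "dinner")
  d <- extract_windows(stream, meals, grid = g)
  expect_equal(as.vector(d$Y[1, ]), c(101, 102, 103))
  # observations 3 min away from every target: all out of tolerance
  stream2 <- tibble::tibble(subject_id = "S001",
                            time = t0 + c(-3, 13) * 60,
                            glucose = c(90, 91))
  d2 <- suppressWarnings(extract_windows(stream2, meals, grid = g))
  expect_equal(nrow(d2$Y), 0)
})
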