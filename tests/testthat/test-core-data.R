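test_that("trimmed daily aggregation follows the missing-hour and trim rules", {
  # more than 3 missing hourly readings -> day is missing
  v <- c(rep(10, 20), rep(NA, 4))
  expect_true(is.na(aggregate_hourly_to_daily(v)))
  expect_equal(aggregate_hourly_to_daily(c(rep(10, 21), rep(NA, 3))), 10)
  # constant series is its own mean
  expect_equal(aggregate_hourly_to_daily(rep(10, 96)), 10)
  # 96 pooled values: floor(96 * 0.025) = 2 dropped per tail
  expect_equal(aggregate_hourly_to_daily(as.numeric(1:96)), mean(3:94))
  expect_equal(aggregate_hourly_to_daily(as.numeric(1:96)), 48.5)
  # all missing is missing, not an error
  expect_true(is.na(aggregate_hourly_to_daily(rep(NA_real_, 24),
                                              max_missing = 30)))
})

test_that("trimmed mean is bounded by the inputs and reduces to the mean", {
  set.seed(41)
  for (i in 1:20) {
    v <- stats::rlnorm(sample(10:80, 1L))
    out <- aggregate_hourly_to_daily(v, trim_frac = 0.05, max_missing = 0)
    expect_gte(out, min(v))
    expect_lte(out, max(v))
    expect_equal(aggregate_hourly_to_daily(v, trim_frac = 0), mean(v))
  }
})

test_that("treatment is the closed North-East sector of wind direction", {
  expect_identical(assign_treatment(45), 1L)
  expect_identical(assign_treatment(225), 0L)
  # closed endpoints
  expect_identical(assign_treatment(c(10, 90)), c(1L, 1L))
  expect_identical(assign_treatment(c(9.99, 90.01)), c(0L, 0L))
  expect_error(assign_treatment(400), "0, 360")
  # sector wrapping through North
  expect_identical(assign_treatment(c(350, 5, 20), sector = c(340, 10)),
                   c(1L, 1L, 0L))
})

test_that("CSV ingestion validates, derives fields, and round-trips", {
  df <- make_daily(3L)
  path <- tempfile(fileext = ".csv")
  write_daily_dataset(df, path)
  back <- read_daily_dataset(path)
  expect_s3_class(back, "daily_dataset")
  expect_identical(back$julian, 0:2)
  expect_identical(back$w, df$w)

  # round trip preserves every non-missing value of a noisy table
  synth <- generate_dataset(synthetic_config(n_days = 40), seed = 3)$data
  synth$pm2_5[5:8] <- NA
  p2 <- tempfile(fileext = ".csv")
  write_daily_dataset(synth, p2)
  back2 <- read_daily_dataset(p2)
  for (v in c("temperature", "wind_direction", "pm10", "pm2_5")) {
    expect_equal(back2[[v]], synth[[v]], tolerance = 1e-12)
  }

  bad <- as.data.frame(make_daily(3L))
  bad$wind_direction[2L] <- 400
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  expect_error(read_daily_dataset(p3), "wind_direction.*row.*2")

  dup <- as.data.frame(make_daily(3L))
  dup$date[3L] <- dup$date[2L]
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(dup, p4, row.names = FALSE)
  expect_error(read_daily_dataset(p4), "duplicate")

  # schema mapping
  ren <- as.data.frame(make_daily(3L))
  names(ren)[names(ren) == "pm10"] <- "PM10"
  p5 <- tempfile(fileext = ".csv")
  utils::write.csv(ren, p5, row.names = FALSE)
  mapped <- read_daily_dataset(p5, schema = c(pm10 = "PM10"))
  expect_equal(mapped$pm10, df$pm10)
})

test_that("lags and leads are calendar-based", {
  d <- make_daily(3L, pm10 = c(1, 2, 3))
  d <- add_lags_and_leads(d, "pm10", c(-1L, 1L))
  expect_equal(d$pm10_lag1, c(NA, 1, 2))
  expect_equal(d$pm10_lead1, c(2, 3, NA))

  # a 2-day hole in the calendar: the lag across it is missing
  gap <- make_daily(5L, pm10 = c(5, 6, 7, 8, 9))
  gap <- as.data.frame(gap)
  gap$date[4:5] <- gap$date[4:5] + 2L
  gap <- add_lags_and_leads(as_daily_dataset(gap), "pm10", -1L)
  expect_equal(gap$pm10_lag1, c(NA, 5, 6, NA, 8))

  expect_error(add_lags_and_leads(d, "nope", -1L), "unknown variable")

  # lead and lag are mutually inverse shifts: the lead value seen on day
  # d is the lag value seen two days later, and both recover the series
  s <- generate_dataset(synthetic_config(n_days = 60), seed = 5)$data
  s <- add_lags_and_leads(s, "pm10", c(-1L, 1L))
  n <- nrow(s)
  expect_equal(s$pm10_lead1[1:(n - 2L)], s$pm10_lag1[3:n])
  expect_equal(s$pm10_lead1[-n], s$pm10[-1L])
  expect_equal(s$pm10_lag1[-1L], s$pm10[-n])
})

test_that("treatment indicator is consistent dataset-wide", {
  s <- generate_dataset(synthetic_config(n_days = 400), seed = 11)$data
  expect_identical(s$w, assign_treatment(s$wind_direction,
                                         attr(s, "sector")))
})

test_that("chained imputation fills flagged cells and respects exclusions", {
  # complete data: values unchanged, no flag set
  full <- make_daily(30L, pm10 = stats::rnorm(30, 20))
  out <- impute_missing(full, learner = "linear", seed = 1)
  expect_equal(out$pm10, full$pm10)
  flags <- out[, grep("^imputed_", names(out))]
  expect_false(any(as.matrix(flags)))

  # y = 2 x with one y missing: a linear learner recovers it
  n <- 40L
  x <- seq_len(n) / 2
  y <- 2 * x
  y[17L] <- NA
  d <- make_daily(n, no2 = x, pm10 = y)
  imp <- impute_missing(d, learner = "linear", seed = 1)
  expect_equal(imp$pm10[17L], 2 * x[17L], tolerance = 1e-6)
  expect_true(imp$imputed_pm10[17L])
  expect_equal(sum(imp$imputed_pm10), 1L)

  # excluded variables keep their missing cells
  d2 <- make_daily(n, pm2_5 = replace(stats::rnorm(n, 12), 4:6, NA),
                   pm10 = replace(stats::rnorm(n, 20), 10, NA))
  imp2 <- impute_missing(d2, exclude = "pm2_5", learner = "linear", seed = 1)
  expect_true(all(is.na(imp2$pm2_5[4:6])))
  expect_false(anyNA(imp2$pm10))

  # a variable with no observed values is rejected
  d3 <- make_daily(n, pm10 = NA_real_)
  expect_error(impute_missing(d3, learner = "linear"), "no observed values")

  # deterministic given the seed (random-forest learner)
  d4 <- generate_dataset(synthetic_config(n_days = 80), seed = 2)$data
  d4$no2[c(3, 10, 44)] <- NA
  a <- impute_missing(d4, seed = 9)
  b <- impute_missing(d4, seed = 9)
  expect_identical(a$no2, b$no2)
})

test_that("imputation evaluation reports per-variable MAE reproducibly", {
  d <- make_daily(60L, pm10 = 20)  # constant column: perfect imputation
  ev <- evaluate_imputation(d, mask_fraction = 0.2, variables = "pm10",
                            learner = "linear", seed = 1)
  expect_equal(ev$mae[ev$variable == "pm10"], 0, tolerance = 1e-8)
  expect_equal(ev$observed_mean[ev$variable == "pm10"], 20)

  expect_error(evaluate_imputation(d, mask_fraction = 1.2), "mask_fraction")

  s <- generate_dataset(synthetic_config(n_days = 120), seed = 4)$data
  e1 <- evaluate_imputation(s, 0.1, variables = "no2", learner = "linear",
                            seed = 21)
  e2 <- evaluate_imputation(s, 0.1, variables = "no2", learner = "linear",
                            seed = 21)
  e3 <- evaluate_imputation(s, 0.1, variables = "no2", learner = "linear",
                            seed = 22)
  expect_identical(e1$mae, e2$mae)
  expect_false(identical(e1$mae, e3$mae))  # different mask per seed
})
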