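# two treated and two control days whose admissible distances form the
# matrix [[1.07, 2.13], [2.13, 1.07]] (covariates contribute 1 or 2,
# dates 4/60 or 8/60); no lagged or exact variables involved
cross_fixture <- function() {
  df <- data.frame(
    date = as.Date("2014-06-02") + c(0, 4, 8, 12),    # t1 c1 c2 t2
    temperature = c(10, 5, 5, 0),
    humidity = c(50, 50, 62, 62),
    wind_speed = 3,
    wind_direction = c(45, 200, 200, 45),
    rainfall_cat = 1, holiday = 0, bank_day = 0,
    no2 = 30, o3 = 40, pm10 = c(25, 18, 21, 26), pm2_5 = 12)
  list(data = as_daily_dataset(df),
       constraints = matching_constraints(
         exact_vars = character(),
         calipers = c(temperature = 5, humidity = 12)))
}

test_that("admissibility enforces calipers, exact variables and date gaps", {
  wd <- rep(200, 61)
  wd[8L] <- 45                                 # one treated Monday
  base <- make_daily(61L, wind_direction = wd)
  base <- add_lags_and_leads(base, c("w", "pm10"), -1L)
  tr <- base[8L, , drop = FALSE]               # treated, with observed lags
  ct <- base[32L, , drop = FALSE]              # a weekday 24 days later

  expect_true(admissible(tr, ct))

  ct_far <- base[11L, , drop = FALSE]          # date gap 3: interference risk
  expect_false(admissible(tr, ct_far))
  expect_true(admissible(tr, base[12L, , drop = FALSE]))  # gap 4 allowed

  ct_hot <- ct
  ct_hot$temperature <- tr$temperature + 6     # beyond the 5 degree caliper
  expect_false(admissible(tr, ct_hot))
  ct_edge <- ct
  ct_edge$temperature <- tr$temperature + 5    # closed caliper boundary
  expect_true(admissible(tr, ct_edge))

  ct_rain <- ct
  ct_rain$rainfall_cat <- 3                    # exact variable differs
  expect_false(admissible(tr, ct_rain))

  ct_na <- ct
  ct_na$humidity <- NA                         # missing covariate: logged out
  expect_false(admissible(tr, ct_na))

  # stricter both-zero rule on the lagged treatment indicator
  strict <- matching_constraints(lag_w_rule = "both_zero")
  tr1 <- tr
  tr1$w_lag1 <- 1L
  ct1 <- ct
  ct1$w_lag1 <- 1L
  expect_true(admissible(tr1, ct1))
  expect_false(admissible(tr1, ct1, strict))
})

test_that("pair distance is the caliper-normalised L1 metric", {
  f <- cross_fixture()
  t1 <- f$data[1L, , drop = FALSE]
  expect_equal(pair_distance(t1, f$data[2L, , drop = FALSE], f$constraints),
               1 + 4 / 60)
  expect_equal(pair_distance(t1, f$data[3L, , drop = FALSE], f$constraints),
               2 + 8 / 60)

  # the documented arithmetic: gaps (2, 0.2, 6, 4, 12 days) under the
  # default calipers sum to 2/5 + 0.2/0.5 + 6/12 + 4/8 + 12/60 = 2
  base <- make_daily(40L)
  base <- add_lags_and_leads(base, c("w", "pm10"), -1L)
  tr <- base[10L, , drop = FALSE]
  tr$w <- 1L
  ct <- base[22L, , drop = FALSE]              # 12 days apart
  ct$temperature <- tr$temperature + 2
  ct$wind_speed <- tr$wind_speed + 0.2
  ct$humidity <- tr$humidity + 6
  ct$pm10_lag1 <- tr$pm10_lag1 + 4
  expect_equal(pair_distance(tr, ct), 2)

  # identical covariates at gap 0 give distance 0; doubling all gaps
  # doubles the distance
  ct0 <- tr
  ct0$w <- 0L
  cz <- matching_constraints(min_date_gap = 0L,
                             exact_vars = character(),
                             calipers = c(temperature = 5, humidity = 12))
  expect_equal(pair_distance(tr, ct0, cz), 0)
  ct2 <- ct
  ct2$date <- tr$date + 24
  ct2$temperature <- tr$temperature + 4
  ct2$wind_speed <- tr$wind_speed + 0.4
  ct2$humidity <- tr$humidity + 12
  ct2$pm10_lag1 <- tr$pm10_lag1 + 8
  expect_equal(pair_distance(tr, ct2), 4)

  expect_error(pair_distance(tr, base[11L, , drop = FALSE]),
               "admissible")
})

test_that("optimal matching solves the crossed two-by-two instance", {
  f <- cross_fixture()
  m <- match_pairs(f$data, f$constraints)
  expect_equal(m$J, 2L)
  # t1 (row 1) with c1 (row 2); t2 (row 4) with c2 (row 3)
  expect_equal(sort(paste(m$pairs$treated_id, m$pairs$control_id)),
               sort(c("1 2", "4 3")))
  expect_equal(sum(m$pairs$distance), 2 + 8 / 60)

  oracle <- dp_oracle_match(oracle_cost_matrix(f$data, f$constraints))
  expect_equal(m$J, oracle$cardinality)
  expect_equal(sum(m$pairs$distance), oracle$total_distance,
               tolerance = 1e-8)
})

test_that("matching handles empty edge sets and stays deterministic", {
  none <- make_daily(10L)   # no treated day at all
  m0 <- match_pairs(none)
  expect_equal(m0$J, 0L)
  expect_equal(m0$matched_fraction, 0)

  f <- cross_fixture()
  m1 <- match_pairs(f$data, f$constraints)
  m2 <- match_pairs(f$data, f$constraints)
  expect_identical(m1$pairs, m2$pairs)
})

test_that("matching equals exhaustive enumeration on random small instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    m <- match_pairs(inst$data, inst$constraints)
    oracle <- dp_oracle_match(oracle_cost_matrix(inst$data,
                                                 inst$constraints))
    expect_equal(m$J, oracle$cardinality, info = paste("seed", seed))
    expect_equal(sum(m$pairs$distance), oracle$total_distance,
                 tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("returned pairs are disjoint and admissible, and greedy never beats optimal", {
  s <- generate_dataset(synthetic_config(n_days = 1200), seed = 23)$data
  m <- match_pairs(s)
  ids <- c(m$pairs$treated_id, m$pairs$control_id)
  expect_equal(anyDuplicated(ids), 0L)
  expect_lte(m$J, min(m$n_treated, m$n_control))

  g <- match_pairs(s, method = "greedy")
  expect_lte(g$J, m$J)
  gids <- c(g$pairs$treated_id, g$pairs$control_id)
  expect_equal(anyDuplicated(gids), 0L)
  data_l <- m$data   # includes the derived lag columns
  ok <- vapply(seq_len(g$J), function(j) {
    admissible(data_l[g$pairs$treated_id[j], , drop = FALSE],
               data_l[g$pairs$control_id[j], , drop = FALSE],
               g$constraints)
  }, logical(1L))
  expect_true(all(ok))
})

test_that("relaxing a caliper weakly increases the matched count", {
  s <- generate_dataset(synthetic_config(n_days = 800), seed = 31)$data
  tight <- matching_constraints(calipers = c(temperature = 2,
                                             wind_speed = 0.5,
                                             humidity = 12, pm10_lag1 = 8))
  loose <- matching_constraints(calipers = c(temperature = 8,
                                             wind_speed = 0.5,
                                             humidity = 12, pm10_lag1 = 8))
  expect_lte(match_pairs(s, tight)$J, match_pairs(s, loose)$J)
})

test_that("matching summary reports counts and the matched fraction", {
  f <- cross_fixture()
  m <- match_pairs(f$data, f$constraints)
  sm <- matching_summary(f$data, m, covariates = c("temperature", "humidity"))
  expect_equal(sm$counts$J, 2L)
  expect_equal(sm$counts$matched_fraction, 1)   # both treated matched
  expect_equal(nrow(sm$covariate_means), 2L)

  none <- match_pairs(make_daily(10L))
  sm0 <- matching_summary(make_daily(10L), none,
                          covariates = "temperature")
  expect_equal(sm0$counts$matched_fraction, 0)
  # the fraction is reported to 3 decimals: e.g. 121 of 912 -> 0.133
  expect_equal(round(121 / 912, 3L), 0.133)
})
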