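test_that("pair differences subtract control from treated and drop incomplete pairs", {
  d <- make_daily(12L, wind_direction = c(rep(45, 3), rep(200, 9)),
                  pm10 = c(10, 11, 12, 7, 8, 9, rep(20, 6)),
                  pm2_5 = c(5, NA, 6, 4, 4, NA, rep(12, 6)))
  fd <- fake_design(d, t_ids = 1:3, c_ids = 4:6)
  expect_equal(as.numeric(pair_differences(d, fd, "pm10")), c(3, 3, 3))
  # pairs with a missing member are dropped listwise, with a count
  dd <- pair_differences(d, fd, "pm2_5")
  expect_equal(as.numeric(dd), 5 - 4)
  expect_equal(attr(dd, "n_dropped"), 2L)
  expect_error(pair_differences(d, fake_design(d, 2L, 6L), "pm2_5"),
               "complete")
  # offset -1 reaches the previous day's values
  d2 <- add_lags_and_leads(d, "pm10", -1L)
  lag_diff <- pair_differences(d2, fake_design(d2, 2:3, 5:6), "pm10", -1L)
  expect_equal(as.numeric(lag_diff), c(10 - 7, 11 - 8))
})

test_that("Neyman estimate, conservative variance and Gaussian intervals", {
  est <- neyman_estimate(c(2, 4, 6))
  expect_equal(est$tau_hat, 4)
  expect_equal(est$var_hat, 8 / 6)
  expect_equal(est$ci95, c(1.737, 6.263), tolerance = 5e-4)
  expect_equal(est$ci99, 4 + c(-1, 1) * 2.576 * sqrt(8 / 6),
               tolerance = 1e-10)
  # ci95 nested in ci99, centred on tau_hat
  expect_gte(est$ci95[1L], est$ci99[1L])
  expect_lte(est$ci95[2L], est$ci99[2L])
  expect_equal(mean(est$ci95), est$tau_hat)

  flat <- neyman_estimate(rep(3.5, 8))
  expect_equal(flat$var_hat, 0)
  expect_equal(flat$ci95, c(3.5, 3.5))

  expect_error(neyman_estimate(2), "at least 2")

  # oracle: var_hat is the textbook variance of the mean of the d_j
  set.seed(12)
  d <- stats::rnorm(25, 4, 3)
  expect_equal(neyman_estimate(d)$var_hat, stats::var(d) / length(d))

  # equivariance: adding c to every treated outcome shifts tau_hat by c
  shift <- neyman_estimate(d + 2.5)
  expect_equal(shift$tau_hat, neyman_estimate(d)$tau_hat + 2.5)
  expect_equal(shift$var_hat, neyman_estimate(d)$var_hat)

  rel <- neyman_estimate(c(2, 4, 6), control_mean = 20)
  expect_equal(rel$relative_increase, 20)
})

test_that("lead/lag table is constant across offsets for a time-constant outcome", {
  n <- 30L
  d <- make_daily(n, wind_direction = rep(c(45, 200, 200), 10L),
                  pm10 = 20 + (seq_len(n) %% 3))  # depends only on position
  # outcome truly constant over time:
  d$pm10 <- 25
  d$o3 <- 40
  fd <- fake_design(d, t_ids = c(4L, 7L, 10L), c_ids = c(5L, 8L, 11L))
  tab <- lead_lag_effects(d, fd, outcomes = c("pm10", "o3"))
  expect_equal(nrow(tab), 6L)
  for (o in c("pm10", "o3")) {
    sub <- tab[tab$outcome == o, ]
    expect_equal(sub$tau_hat, rep(sub$tau_hat[1L], 3L))
    expect_equal(sub$se, rep(sub$se[1L], 3L))
  }
})

test_that("matched estimates recover a known synthetic effect", {
  s <- generate_dataset(synthetic_config(n_days = 2500), seed = 42)
  m <- match_pairs(s$data)
  tab <- lead_lag_effects(m$data, m, outcomes = c("pm10", "no2"),
                          offsets = c(-1L, 0L))
  pm0 <- tab[tab$outcome == "pm10" & tab$offset == 0L, ]
  expect_gt(pm0$ci95_high, 5)  # true tau
  expect_lt(pm0$ci95_low, 5)
  expect_equal(true_tau_fs(s, m, "pm10"), 5)
  # null outcome: interval straddles zero at this seed
  no2_0 <- tab[tab$outcome == "no2" & tab$offset == 0L, ]
  expect_lt(no2_0$ci95_low, 0)
  expect_gt(no2_0$ci95_high, 0)
})

test_that("complete-randomization variance comparison matches hand arithmetic", {
  d <- make_daily(8L, wind_direction = c(45, 45, rep(200, 6)),
                  pm10 = c(10, 12, 7, 9, rep(20, 4)))
  fd <- fake_design(d, t_ids = 1:2, c_ids = 3:4)
  pr <- complete_randomization_variance(d, fd, "pm10")
  # d_j = (3, 3): pairwise variance 0; complete = var(10,12)/2 + var(7,9)/2
  expect_equal(pr$se_pairwise, 0)
  expect_equal(pr$var_complete, 2)
  expect_equal(pr$se_complete, sqrt(2))
  expect_equal(pr$precision_ratio, Inf)

  # when pairing is uninformative the two variances agree in expectation
  set.seed(99)
  ratios <- replicate(200, {
    dd <- make_daily(80L, wind_direction = rep(c(45, 200), each = 40L),
                     pm10 = stats::rnorm(80, 15, 2))
    fdd <- fake_design(dd, t_ids = 1:40, c_ids = sample(41:80))
    pr <- complete_randomization_variance(dd, fdd, "pm10")
    pr$var_complete / pr$se_pairwise^2
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})
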