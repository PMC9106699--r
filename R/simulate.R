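#' Configuration of the synthetic daily-data generator
#'
#' Builds the parameter set for [generate_dataset()]. The defaults emulate
#' a decade of daily observations for a mid-latitude city: a sinusoidal
#' annual temperature cycle with AR(1) noise, a seasonally weighted mixture
#' of wrapped-normal wind-direction components (one centred inside the
#' North-East sector, so that roughly a quarter of days are treated),
#' gamma-distributed wind speed, bounded seasonal humidity, ordinal
#' rainfall-duration categories, and pollutant baselines driven by season,
#' temperature and wind speed with day-to-day AR(1) persistence. Treatment
#' adds a constant `tau` (ug/m3) to the potential outcome under North-East
#' wind; by default only the particulate-matter series have a non-zero
#' effect.
#'
#' @param n_days number of consecutive days (>= 30).
#' @param start_date first calendar date.
#' @param sector treated wind-direction sector in degrees (closed).
#' @param temperature list: `mean`, `amplitude` (degrees C), `peak_doy`
#'   (day of year of the seasonal maximum), `ar` (AR(1) coefficient of the
#'   residual), `sd` (innovation standard deviation).
#' @param wind list: `mean` and `sd` (degrees) of the wrapped-normal
#'   mixture components, `weights` (must sum to 1), `ne_component` (index
#'   of the component centred in the treated sector), `ne_seasonal_amp`
#'   and `ne_peak_doy` controlling the seasonal modulation of that
#'   component's weight (the other weights are rescaled day by day so the
#'   mixture still sums to 1).
#' @param wind_speed list: gamma `shape` and `scale` (m/s).
#' @param humidity list: `mean`, `amplitude`, `peak_doy`, `sd` (percent;
#'   values are truncated to `[0, 100]`).
#' @param rainfall_probs probabilities of the four ordinal categories.
#' @param holiday_prob,bank_day_prob daily probabilities of the calendar
#'   indicators.
#' @param pollutants named list (one entry per pollutant) of lists:
#'   `intercept`, `amplitude`, `peak_doy`, `temp_slope`, `ws_slope`, `ar`,
#'   `sd` — the control potential outcome is
#'   intercept + seasonal cycle + slopes x weather + AR(1) residual.
#' @param tau named additive treatment effects (ug/m3), constant across
#'   days by default.
#' @param tau_sd named day-to-day standard deviations of the treatment
#'   effect (0 = constant effect; non-zero gives heterogeneous effects for
#'   conservativeness experiments).
#' @param confounder list: `prevalence` of a hidden binary confounder U,
#'   `gamma` (multiplier of the treatment odds on days with U = 1) and
#'   `delta` (shift added to both potential outcomes of every pollutant on
#'   those days). The default `gamma = 1`, `delta = 0` is an inert
#'   confounder, i.e. no hidden bias.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_days = 4018L,
                             start_date = as.Date("2008-01-01"),
                             sector = c(10, 90),
                             temperature = list(mean = 12, amplitude = 8,
                                                peak_doy = 200, ar = 0.7,
                                                sd = 2.5),
                             wind = list(mean = c(50, 230, 330),
                                         sd = c(25, 45, 35),
                                         weights = c(0.25, 0.50, 0.25),
                                         ne_component = 1L,
                                         ne_seasonal_amp = 0.08,
                                         ne_peak_doy = 150),
                             wind_speed = list(shape = 4, scale = 0.9),
                             humidity = list(mean = 75, amplitude = 10,
                                             peak_doy = 15, sd = 8),
                             rainfall_probs = c(0.25, 0.25, 0.25, 0.25),
                             holiday_prob = 0.25,
                             bank_day_prob = 0.03,
                             pollutants = list(
                               no2   = list(intercept = 50, amplitude = 6,
                                            peak_doy = 15, temp_slope = -0.4,
                                            ws_slope = -2.5, ar = 0.6, sd = 8),
                               o3    = list(intercept = 30, amplitude = 12,
                                            peak_doy = 200, temp_slope = 1.2,
                                            ws_slope = 0.5, ar = 0.5, sd = 9),
                               pm10  = list(intercept = 32, amplitude = 4,
                                            peak_doy = 30, temp_slope = -0.3,
                                            ws_slope = -1.5, ar = 0.6, sd = 7),
                               pm2_5 = list(intercept = 22, amplitude = 4,
                                            peak_doy = 30, temp_slope = -0.25,
                                            ws_slope = -1.2, ar = 0.65,
                                            sd = 5)),
                             tau = c(no2 = 0, o3 = 0, pm10 = 5, pm2_5 = 1.5),
                             tau_sd = c(no2 = 0, o3 = 0, pm10 = 0, pm2_5 = 0),
                             confounder = list(prevalence = 0.2, gamma = 1,
                                               delta = 0)) {
  cfg <- list(n_days = as.integer(n_days), start_date = as.Date(start_date),
              sector = sector, temperature = temperature, wind = wind,
              wind_speed = wind_speed, humidity = humidity,
              rainfall_probs = rainfall_probs, holiday_prob = holiday_prob,
              bank_day_prob = bank_day_prob, pollutants = pollutants,
              tau = tau, tau_sd = tau_sd, confounder = confounder)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_days < 30L) stop("n_days must be at least 30")
  sds <- c(cfg$temperature$sd, cfg$wind$sd, cfg$humidity$sd,
           vapply(cfg$pollutants, `[[`, numeric(1L), "sd"), cfg$tau_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  w <- cfg$wind$weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("wind mixture weights must be non-negative and sum to 1")
  }
  ne <- cfg$wind$ne_component
  if (w[ne] + abs(cfg$wind$ne_seasonal_amp) >= 1 ||
      w[ne] - abs(cfg$wind$ne_seasonal_amp) <= 0) {
    stop("seasonal amplitude drives the NE mixture weight outside (0, 1)")
  }
  if (abs(sum(cfg$rainfall_probs) - 1) > 1e-8 || any(cfg$rainfall_probs < 0)) {
    stop("rainfall_probs must be a probability vector over 4 categories")
  }
  if (cfg$confounder$gamma < 1) stop("confounder gamma must be >= 1")
  invisible(cfg)
}

# annual cosine cycle
.seasonal <- function(doy, mean, amplitude, peak_doy) {
  mean + amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

# stationary AR(1) residual series with innovation sd
.ar1 <- function(n, ar, sd) {
  if (sd == 0) return(numeric(n))
  r1 <- stats::rnorm(1L, 0, sd / sqrt(max(1 - ar^2, 1e-12)))
  innov <- stats::rnorm(n - 1L, 0, sd)
  c(r1, stats::filter(innov, ar, method = "recursive", init = r1))
}

# mass of a wrapped normal (mu, sd in degrees) inside [lo, hi] on the circle
.sector_prob <- function(mu, sd, lo, hi) {
  k <- -2:2
  sum(stats::pnorm(hi + 360 * k, mu, sd) - stats::pnorm(lo + 360 * k, mu, sd))
}

#' Generate a synthetic daily dataset with known potential outcomes
#'
#' Simulates weather, treatment and pollutant series according to a
#' [synthetic_config()]. For every day both potential outcomes Y(0) and
#' Y(1) of each pollutant are generated and stored in a hidden truth
#' table; the observed concentration is `(1 - W) * Y(0) + W * Y(1)` where
#' `W` indicates North-East wind. Wind direction is drawn in two steps —
#' first the treated-sector indicator (whose probability follows the
#' seasonal mixture, with the odds multiplied by the configured confounder
#' gamma on hidden-confounder days), then a direction from the mixture
#' restricted to the corresponding part of the circle — so the hidden bias
#' mechanism is exactly an odds multiplier on treatment.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the output is reproducible given the seed.
#' @return A `synthetic_dataset`: list with `data` (the observed
#'   `daily_dataset`), `truth` (data frames `y0`, `y1`, vector `u`, the
#'   effect vectors) and the config.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1L) {
  validate_synthetic_config(config)
  set.seed(seed)
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  doy <- as.integer(format(dates, "%j"))

  # --- weather ---------------------------------------------------------
  tp <- config$temperature
  temperature <- .seasonal(doy, tp$mean, tp$amplitude, tp$peak_doy) +
    .ar1(n, tp$ar, tp$sd)
  wind_speed <- stats::rgamma(n, shape = config$wind_speed$shape,
                              scale = config$wind_speed$scale)
  hm <- config$humidity
  humidity <- pmin(pmax(.seasonal(doy, hm$mean, hm$amplitude, hm$peak_doy) +
                          stats::rnorm(n, 0, hm$sd), 0), 100)
  rainfall_cat <- sample.int(4L, n, replace = TRUE,
                             prob = config$rainfall_probs)
  holiday <- stats::rbinom(n, 1L, config$holiday_prob)
  bank_day <- stats::rbinom(n, 1L, config$bank_day_prob)

  # --- treatment and wind direction ------------------------------------
  wd <- config$wind
  ne <- wd$ne_component
  w_ne <- wd$weights[ne] +
    wd$ne_seasonal_amp * cos(2 * pi * (doy - wd$ne_peak_doy) / 365.25)
  other <- setdiff(seq_along(wd$weights), ne)
  wmat <- matrix(0, n, length(wd$weights))
  wmat[, ne] <- w_ne
  for (j in other) {
    wmat[, j] <- wd$weights[j] * (1 - w_ne) / sum(wd$weights[other])
  }
  p_in <- vapply(seq_along(wd$weights), function(j) {
    .sector_prob(wd$mean[j], wd$sd[j], config$sector[1L], config$sector[2L])
  }, numeric(1L))
  p_treat <- drop(wmat %*% p_in)

  u <- stats::rbinom(n, 1L, config$confounder$prevalence)
  gam <- config$confounder$gamma
  odds <- p_treat / (1 - p_treat) * ifelse(u == 1L, gam, 1)
  p_w <- odds / (1 + odds)
  w <- as.integer(stats::runif(n) < p_w)

  wind_direction <- .draw_direction(wmat, wd, p_in, w, config$sector)

  # --- potential outcomes ----------------------------------------------
  y0 <- y1 <- as.data.frame(matrix(NA_real_, n, length(config$pollutants)))
  names(y0) <- names(y1) <- names(config$pollutants)
  delta <- config$confounder$delta
  for (p in names(config$pollutants)) {
    pp <- config$pollutants[[p]]
    base <- .seasonal(doy, pp$intercept, pp$amplitude, pp$peak_doy) +
      pp$temp_slope * temperature + pp$ws_slope * wind_speed +
      .ar1(n, pp$ar, pp$sd) + delta * u
    eff <- config$tau[[p]]
    if (config$tau_sd[[p]] > 0) {
      eff <- eff + stats::rnorm(n, 0, config$tau_sd[[p]])
    }
    y0[[p]] <- base
    y1[[p]] <- base + eff
  }

  obs <- data.frame(date = dates, temperature = temperature,
                    wind_speed = wind_speed,
                    wind_direction = wind_direction, humidity = humidity,
                    rainfall_cat = rainfall_cat, holiday = holiday,
                    bank_day = bank_day)
  for (p in names(y0)) obs[[p]] <- (1 - w) * y0[[p]] + w * y1[[p]]
  data <- as_daily_dataset(obs, sector = config$sector)
  stopifnot(identical(data$w, w))

  structure(list(data = data,
                 truth = list(y0 = y0, y1 = y1, u = u, tau = config$tau,
                              tau_sd = config$tau_sd),
                 config = config, seed = seed),
            class = "synthetic_dataset")
}

# sample wind directions from the mixture conditional on sector membership
.draw_direction <- function(wmat, wd, p_in, w, sector) {
  n <- nrow(wmat)
  m <- length(wd$mean)
  cond <- wmat * matrix(rep(p_in, each = n), n, m)   # P(comp & in sector)
  cond[w == 0L, ] <- (wmat * matrix(rep(1 - p_in, each = n), n, m))[w == 0L, ]
  cond <- cond / rowSums(cond)
  dir <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    u_comp <- stats::runif(length(todo))
    cum <- t(apply(cond[todo, , drop = FALSE], 1L, cumsum))
    comp <- 1L + rowSums(cum < u_comp)
    cand <- (stats::rnorm(length(todo), wd$mean[comp], wd$sd[comp])) %% 360
    inside <- assign_treatment(cand, sector)
    ok <- inside == w[todo]
    dir[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  dir
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic daily dataset (seed ", x$seed, ")\n", sep = "")
  print(x$data)
  cat("True additive effects (ug/m3): ",
      paste(names(x$truth$tau), round(unlist(x$truth$tau), 2), sep = " = ",
            collapse = ", "), "\n", sep = "")
  if (x$config$confounder$gamma > 1) {
    cat("Hidden confounder: prevalence ", x$config$confounder$prevalence,
        ", treatment-odds multiplier ", x$config$confounder$gamma,
        ", outcome shift ", x$config$confounder$delta, "\n", sep = "")
  }
  invisible(x)
}

#' True finite-sample effect for a matched subset
#'
#' Averages the hidden unit-level effects `Y(1) - Y(0)` over the treated
#' members of a matched-pair set; with the constant-effect default this is
#' exactly the configured `tau`.
#'
#' @param synth a `synthetic_dataset`.
#' @param pairs a [matched_design] built on `synth$data`.
#' @param pollutant pollutant name.
#' @return The finite-sample average treatment effect for matched treated
#'   units.
#' @export
true_tau_fs <- function(synth, pairs, pollutant) {
  stopifnot(inherits(synth, "synthetic_dataset"))
  idx <- pairs$pairs$treated_id
  mean(synth$truth$y1[[pollutant]][idx] - synth$truth$y0[[pollutant]][idx])
}

#' Remove observations completely at random
#'
#' Masks cells of the observed view with the requested per-variable
#' probabilities (missing completely at random by default, or missing at
#' random given temperature with `mechanism = "mar_temperature"`, which
#' doubles the odds of masking on days warmer than the median). Hidden
#' potential outcomes are untouched.
#'
#' @param x a `synthetic_dataset` or `daily_dataset`.
#' @param rates named vector of missingness proportions in `[0, 1)`.
#' @param seed integer seed.
#' @param mechanism `"mcar"` or `"mar_temperature"`.
#' @return Object of the same class with masked cells.
#' @export
inject_missingness <- function(x, rates, seed = 1L,
                               mechanism = c("mcar", "mar_temperature")) {
  mechanism <- match.arg(mechanism)
  stopifnot(all(rates >= 0), all(rates < 1), !is.null(names(rates)))
  data <- if (inherits(x, "synthetic_dataset")) x$data else x
  set.seed(seed)
  n <- nrow(data)
  for (v in names(rates)) {
    if (!v %in% names(data)) stop("unknown variable: ", v)
    r <- rates[[v]]
    if (r == 0) next
    p <- rep(r, n)
    if (mechanism == "mar_temperature") {
      warm <- data$temperature > stats::median(data$temperature, na.rm = TRUE)
      odds <- r / (1 - r) * ifelse(warm, 2, 1)
      p <- odds / (1 + odds)
      p <- p * r * n / sum(p)   # keep the marginal rate at r
    }
    data[[v]][stats::runif(n) < p] <- NA
  }
  if (inherits(x, "synthetic_dataset")) {
    x$data <- data
    x
  } else {
    data
  }
}

#' Generate a dataset with a hidden confounder
#'
#' Convenience wrapper around [generate_dataset()] that switches on the
#' unmeasured binary confounder U: on days with U = 1 the odds of
#' North-East wind are multiplied by `gamma_true` and both potential
#' outcomes of every pollutant are shifted by `delta`. U never appears in
#' the observed view, so downstream matching cannot adjust for it — the
#' ground truth for calibrating the quantitative bias analysis.
#'
#' @inheritParams generate_dataset
#' @param gamma_true treatment-odds multiplier, >= 1.
#' @param delta outcome shift (ug/m3) on confounded days.
#' @param prevalence probability that a day is confounded.
#' @export
generate_confounded_dataset <- function(config = synthetic_config(),
                                        gamma_true, delta, seed = 1L,
                                        prevalence = NULL) {
  stopifnot(gamma_true >= 1)
  config$confounder$gamma <- gamma_true
  config$confounder$delta <- delta
  if (!is.null(prevalence)) config$confounder$prevalence <- prevalence
  generate_dataset(config, seed = seed)
}
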