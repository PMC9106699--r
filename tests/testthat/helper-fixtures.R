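# small deterministic daily data frame; override any column via ...
make_daily <- function(n = 10L, start = as.Date("2012-01-02"), ...) {
  df <- data.frame(
    date = start + 0:(n - 1L),
    temperature = 10, wind_speed = 3, wind_direction = 200,
    humidity = 60, rainfall_cat = 1, holiday = 0, bank_day = 0,
    no2 = 30, o3 = 40, pm10 = 20, pm2_5 = 12)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  as_daily_dataset(df)
}

# hand-assembled matched design for inference tests
fake_design <- function(data, t_ids, c_ids) {
  structure(list(
    pairs = data.frame(treated_id = t_ids, control_id = c_ids,
                       treated_date = data$date[t_ids],
                       control_date = data$date[c_ids],
                       distance = 0),
    J = length(t_ids),
    n_treated = sum(data$w == 1L), n_control = sum(data$w == 0L),
    matched_fraction = length(t_ids) / max(sum(data$w == 1L), 1L),
    constraints = matching_constraints(), method = "manual", data = data),
    class = "matched_design")
}

# exhaustive-enumeration oracle for max-cardinality / min-total-distance
# matching: dynamic programme over subsets of controls. cost is an
# nt x nc matrix with NA for inadmissible pairs. Lexicographic objective
# encoded as score = cardinality * 1e6 - total cost (total cost << 1e6).
dp_oracle_match <- function(cost) {
  nt <- nrow(cost)
  nc <- ncol(cost)
  stopifnot(nc <= 12L, all(cost >= 0, na.rm = TRUE),
            sum(cost, na.rm = TRUE) < 1e5)
  n_mask <- bitwShiftL(1L, nc)
  masks <- 0:(n_mask - 1L)
  score <- rep(0, n_mask)           # best score using treated 1..t
  for (t in seq_len(nt)) {
    new <- score                    # leave t unmatched
    for (c in seq_len(nc)) {
      if (is.na(cost[t, c])) next
      bit <- bitwShiftL(1L, c - 1L)
      free <- bitwAnd(masks, bit) == 0L
      from <- masks[free]
      cand <- score[from + 1L] + 1e6 - cost[t, c]
      to <- from + bit + 1L
      new[to] <- pmax(new[to], cand)
    }
    score <- new
  }
  best <- max(score)
  card <- round(best / 1e6)
  list(cardinality = card, total_distance = card * 1e6 - best)
}

# cost matrix for every treated x control pair of a dataset, built from
# the exported admissibility/distance primitives (independent of the
# matching solver)
oracle_cost_matrix <- function(data, constraints) {
  t_rows <- which(data$w == 1L)
  c_rows <- which(data$w == 0L)
  cost <- matrix(NA_real_, length(t_rows), length(c_rows))
  for (i in seq_along(t_rows)) {
    for (j in seq_along(c_rows)) {
      tr <- data[t_rows[i], , drop = FALSE]
      ct <- data[c_rows[j], , drop = FALSE]
      if (admissible(tr, ct, constraints)) {
        cost[i, j] <- pair_distance(tr, ct, constraints)
      }
    }
  }
  cost
}

# random small matching instance: dataset + constraints without lagged
# variables (so tiny fixtures need no lag bookkeeping)
random_instance <- function(seed) {
  set.seed(seed)
  nt <- sample(2:8, 1L)
  nc <- sample(2:10, 1L)
  n <- nt + nc
  dates <- as.Date("2015-03-01") + sort(sample(0:119, n))
  w <- sample(rep(c(1L, 0L), c(nt, nc)))
  df <- data.frame(
    date = dates,
    temperature = round(stats::runif(n, 0, 14), 1),
    wind_speed = round(stats::runif(n, 1, 5), 1),
    wind_direction = ifelse(w == 1L, 50, 220),
    humidity = round(stats::runif(n, 40, 75), 1),
    rainfall_cat = sample(1:2, n, replace = TRUE),
    holiday = 0, bank_day = 0,
    no2 = 30, o3 = 40, pm10 = 20, pm2_5 = 12)
  data <- as_daily_dataset(df)
  constraints <- matching_constraints(
    exact_vars = "rainfall_cat",
    calipers = c(temperature = 6, humidity = 15, wind_speed = 2))
  list(data = data, constraints = constraints)
}

# exact 2^J signed-rank p-value (doubled ranks keep the distribution on
# integers; DP convolution over sign subsets)
exact_sr_p <- function(d, tau0, side = c("greater", "less")) {
  side <- match.arg(side)
  a <- d - tau0
  a <- a[a != 0]
  if (length(a) < 1L) return(1)
  q2 <- as.integer(round(2 * rank(abs(a))))
  maxs <- sum(q2)
  f <- numeric(maxs + 1L)
  f[1L] <- 1
  for (w in q2) {
    g <- f
    g[(w + 1L):(maxs + 1L)] <- g[(w + 1L):(maxs + 1L)] + f[1:(maxs + 1L - w)]
    f <- g
  }
  f <- f / 2^length(q2)
  T2 <- sum(q2[a > 0])
  if (side == "greater") sum(f[(T2 + 1L):(maxs + 1L)])
  else sum(f[1:(T2 + 1L)])
}

# exact-distribution inversion of the two-sided signed-rank test at
# gamma = 1 (bisection on the monotone step functions)
exact_sr_interval <- function(d, alpha = 0.05, tol = 0.005) {
  invert <- function(side, direction) {
    lo <- min(d) - 2 * diff(range(d)) - 1
    hi <- max(d) + 2 * diff(range(d)) + 1
    f <- function(t0) exact_sr_p(d, t0, side)
    if (direction > 0) {
      if (f(lo) > alpha / 2) return(-Inf)
      a <- lo
      b <- max(d)
      while (b - a > tol) {
        m <- (a + b) / 2
        if (f(m) > alpha / 2) b <- m else a <- m
      }
      b
    } else {
      if (f(hi) > alpha / 2) return(Inf)
      a <- min(d)
      b <- hi
      while (b - a > tol) {
        m <- (a + b) / 2
        if (f(m) > alpha / 2) a <- m else b <- m
      }
      a
    }
  }
  c(invert("greater", 1), invert("less", -1))
}
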