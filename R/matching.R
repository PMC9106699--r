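#' Constraints defining admissible treated-control pairs
#'
#' The design stage only compares days that are genuinely exchangeable: a
#' treated (North-East wind) day may be paired with a control day when the
#' calendar gap lies between `min_date_gap` and `max_date_gap` days (the
#' lower bound keeps paired days far enough apart for the no-interference
#' part of SUTVA, the upper bound keeps them within the same season), all
#' `exact_vars` coincide, and every continuous covariate difference is
#' within its caliper (closed, `<=`). Covariates named `<var>_lag1` refer
#' to the previous calendar day and are computed automatically by
#' [match_pairs()] when absent.
#'
#' @param max_date_gap maximum calendar distance in days.
#' @param min_date_gap minimum calendar distance in days (gaps of
#'   `1 .. min_date_gap - 1` are excluded, `min_date_gap` itself allowed).
#' @param exact_vars variables that must be identical within a pair. The
#'   default includes the lagged treatment indicator `w_lag1`, so both
#'   members had the same previous-day wind regime.
#' @param calipers named vector of maximum absolute differences:
#'   temperature (degrees C), wind speed (m/s), humidity (percentage
#'   points), previous-day PM10 (ug/m3).
#' @param lag_w_rule `"equal"` requires the two `w_lag1` values to match;
#'   `"both_zero"` additionally requires them to be 0 (no North-East wind
#'   on either previous day). Only used while `w_lag1` is in `exact_vars`.
#' @return A `matching_constraints` object.
#' @export
matching_constraints <- function(max_date_gap = 60L, min_date_gap = 4L,
                                 exact_vars = c("weekend", "holiday",
                                                "bank_day", "rainfall_cat",
                                                "w_lag1"),
                                 calipers = c(temperature = 5,
                                              wind_speed = 0.5,
                                              humidity = 12,
                                              pm10_lag1 = 8),
                                 lag_w_rule = c("equal", "both_zero")) {
  stopifnot(min_date_gap <= max_date_gap, all(calipers > 0),
            !is.null(names(calipers)))
  out <- list(max_date_gap = as.integer(max_date_gap),
              min_date_gap = as.integer(min_date_gap),
              exact_vars = exact_vars, calipers = calipers,
              lag_w_rule = match.arg(lag_w_rule))
  class(out) <- "matching_constraints"
  out
}

#' @export
print.matching_constraints <- function(x, ...) {
  cat("Matching constraints\n")
  cat("  date gap: ", x$min_date_gap, " to ", x$max_date_gap, " days\n",
      sep = "")
  cat("  exact:    ", paste(x$exact_vars, collapse = ", "), "\n", sep = "")
  cat("  calipers: ",
      paste(names(x$calipers), x$calipers, sep = " <= ", collapse = ", "),
      "\n", sep = "")
  if (x$lag_w_rule == "both_zero" && "w_lag1" %in% x$exact_vars) {
    cat("  previous-day treatment required to be 0 for both members\n")
  }
  invisible(x)
}

# variables a constraint set needs beyond date/w
constraint_vars <- function(constraints) {
  c(constraints$exact_vars, names(constraints$calipers))
}

# lag/lead columns needed and not yet present
.ensure_offset_cols <- function(data, vars) {
  need <- grep("_(lag|lead)[0-9]+$", vars, value = TRUE)
  need <- setdiff(need, names(data))
  for (col in need) {
    m <- regmatches(col, regexec("^(.*)_(lag|lead)([0-9]+)$", col))[[1L]]
    k <- as.integer(m[4L]) * if (m[3L] == "lag") -1L else 1L
    data <- add_lags_and_leads(data, m[2L], k)
  }
  data
}

#' Is a treated-control pair admissible?
#'
#' Checks the full constraint set for one treated day against one or more
#' control days. A pair with a missing value in any constrained covariate
#' is inadmissible (not an error): it cannot be certified comparable.
#'
#' @param treated single row of a `daily_dataset` with `w == 1`.
#' @param control one or more rows with `w == 0`.
#' @param constraints a [matching_constraints()] object.
#' @return Logical vector, one element per control row.
#' @export
admissible <- function(treated, control, constraints = matching_constraints()) {
  stopifnot(nrow(treated) == 1L, treated$w == 1L, all(control$w == 0L))
  gap <- abs(as.integer(control$date - treated$date))
  ok <- gap >= constraints$min_date_gap & gap <= constraints$max_date_gap
  for (v in constraints$exact_vars) {
    eq <- !is.na(treated[[v]]) & !is.na(control[[v]]) &
      control[[v]] == treated[[v]]
    if (v == "w_lag1" && constraints$lag_w_rule == "both_zero") {
      eq <- eq & control[[v]] == 0
    }
    ok <- ok & eq
  }
  for (v in names(constraints$calipers)) {
    dif <- abs(control[[v]] - treated[[v]])
    ok <- ok & !is.na(dif) & dif <= constraints$calipers[[v]]
  }
  ok
}

#' Distance between the members of an admissible pair
#'
#' The normalised L1 distance: the absolute difference in each caliper
#' covariate divided by its caliper width, plus the calendar gap divided
#' by the maximum date gap. Each admissible pair therefore contributes
#' between 0 (coincident covariates) and `length(calipers) + 1`.
#'
#' @inheritParams admissible
#' @return Non-negative numeric vector, one element per control row.
#' @export
pair_distance <- function(treated, control,
                          constraints = matching_constraints()) {
  if (!all(admissible(treated, control, constraints))) {
    stop("pair_distance is only defined for admissible pairs")
  }
  d <- abs(as.integer(control$date - treated$date)) / constraints$max_date_gap
  for (v in names(constraints$calipers)) {
    d <- d + abs(control[[v]] - treated[[v]]) / constraints$calipers[[v]]
  }
  d
}

# admissible edge list over the whole dataset: data.frame(t, c, dist) with
# t, c row indices into data
build_edges <- function(data, constraints) {
  t_rows <- which(data$w == 1L)
  c_rows <- which(data$w == 0L)
  if (!length(t_rows) || !length(c_rows)) {
    return(data.frame(t = integer(), c = integer(), dist = numeric()))
  }
  cdate <- as.integer(data$date[c_rows])
  res_t <- vector("list", length(t_rows))
  for (i in seq_along(t_rows)) {
    ti <- t_rows[i]
    td <- as.integer(data$date[ti])
    # controls within the date window (controls are date-sorted)
    lo <- findInterval(td - constraints$max_date_gap - 1L, cdate) + 1L
    hi <- findInterval(td + constraints$max_date_gap, cdate)
    if (hi < lo) next
    cand <- c_rows[lo:hi]
    ok <- admissible(data[ti, , drop = FALSE],
                     data[cand, , drop = FALSE], constraints)
    cand <- cand[ok]
    if (!length(cand)) next
    dist <- pair_distance(data[ti, , drop = FALSE],
                          data[cand, , drop = FALSE], constraints)
    res_t[[i]] <- data.frame(t = ti, c = cand, dist = dist)
  }
  out <- do.call(rbind, res_t)
  if (is.null(out)) data.frame(t = integer(), c = integer(), dist = numeric())
  else out
}

#' Pair matching without replacement
#'
#' Builds the hypothetical pairwise randomized experiment: every treated
#' day is paired with at most one control day, pairs are disjoint, and
#' among all matchings that pair the largest possible number of treated
#' days the one with the smallest total distance is returned. The default
#' solver casts this two-stage objective as a min-cost flow and solves it
#' exactly; `method = "greedy"` is a documented fallback that walks the
#' treated days in date order and picks each one's nearest free control.
#' Ties are broken towards earlier treated days, then earlier control
#' days.
#'
#' Lag columns referenced by the constraints (`w_lag1`, `pm10_lag1`, ...)
#' are computed on the fly when absent.
#'
#' @param data a `daily_dataset`.
#' @param constraints a [matching_constraints()] object.
#' @param method `"optimal"` (exact) or `"greedy"`.
#' @return A `matched_design` object: the matched pairs (`$pairs`, with
#'   row indices, dates and distances), the pair count `J`, the matched
#'   fraction of treated days, the constraints, and the data the design
#'   was built on.
#' @export
match_pairs <- function(data, constraints = matching_constraints(),
                        method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "data.frame"), "w" %in% names(data))
  data <- .ensure_offset_cols(data, constraint_vars(constraints))
  edges <- build_edges(data, constraints)
  n_treated <- sum(data$w == 1L, na.rm = TRUE)
  n_control <- sum(data$w == 0L, na.rm = TRUE)

  if (nrow(edges) == 0L) {
    pairs <- data.frame(treated_id = integer(), control_id = integer(),
                        treated_date = as.Date(character()),
                        control_date = as.Date(character()),
                        distance = numeric())
  } else {
    t_ids <- sort(unique(edges$t))
    c_ids <- sort(unique(edges$c))
    ti <- match(edges$t, t_ids) - 1L
    ci <- match(edges$c, c_ids) - 1L
    if (method == "optimal") {
      # deterministic tie-breaking: nudge costs towards earlier treated,
      # then earlier control days (well below any real distance scale)
      eps <- 1e-9 * (ti + 1L) / length(t_ids) +
        1e-12 * (ci + 1L) / length(c_ids)
      mt <- min_cost_max_matching(length(t_ids), length(c_ids),
                                  ti, ci, edges$dist + eps)
      sel <- which(mt > 0L)
      pairs <- data.frame(treated_id = t_ids[sel],
                          control_id = c_ids[mt[sel]])
    } else {
      pairs <- greedy_match(edges)
    }
    m <- match(paste(pairs$treated_id, pairs$control_id),
               paste(edges$t, edges$c))
    pairs$treated_date <- data$date[pairs$treated_id]
    pairs$control_date <- data$date[pairs$control_id]
    pairs$distance <- edges$dist[m]
    pairs <- pairs[order(pairs$treated_date), , drop = FALSE]
    rownames(pairs) <- NULL
  }

  structure(list(pairs = pairs, J = nrow(pairs),
                 n_treated = n_treated, n_control = n_control,
                 matched_fraction = if (n_treated) nrow(pairs) / n_treated
                                    else 0,
                 constraints = constraints, method = method, data = data),
            class = "matched_design")
}

# nearest-neighbour matching without replacement, treated in date order
greedy_match <- function(edges) {
  edges <- edges[order(edges$t, edges$dist, edges$c), , drop = FALSE]
  used_c <- integer()
  t_done <- integer()
  out_t <- integer()
  out_c <- integer()
  for (t in unique(edges$t)) {
    sub <- edges[edges$t == t & !(edges$c %in% used_c), , drop = FALSE]
    if (!nrow(sub)) next
    out_t <- c(out_t, t)
    out_c <- c(out_c, sub$c[1L])
    used_c <- c(used_c, sub$c[1L])
  }
  data.frame(treated_id = out_t, control_id = out_c)
}

#' @export
print.matched_design <- function(x, ...) {
  cat("Matched pairwise design (", x$method, " matching)\n", sep = "")
  cat("  treated days:  ", x$n_treated, "\n", sep = "")
  cat("  control days:  ", x$n_control, "\n", sep = "")
  cat("  matched pairs: ", x$J, " (", round(100 * x$matched_fraction, 1),
      "% of treated)\n", sep = "")
  if (x$J) {
    cat("  total distance: ", format(sum(x$pairs$distance), digits = 4),
        "; mean ", format(mean(x$pairs$distance), digits = 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' Diagnostics of a matched design
#'
#' Reports the counts the design stage is judged by — treated days,
#' control days, pair count J and the matched fraction of treated days —
#' together with covariate means in the initial sample and in the matched
#' sample.
#'
#' @param data the `daily_dataset` the pairs were drawn from.
#' @param pairs a `matched_design`.
#' @param covariates covariates to summarise (default: the constraint
#'   covariates present in the data).
#' @return A `matching_summary` list with a `counts` data frame and a
#'   `covariate_means` data frame.
#' @export
matching_summary <- function(data, pairs, covariates = NULL) {
  stopifnot(inherits(pairs, "matched_design"))
  if (is.null(covariates)) {
    covariates <- intersect(constraint_vars(pairs$constraints), names(data))
  }
  counts <- data.frame(n_treated = pairs$n_treated,
                       n_control = pairs$n_control,
                       J = pairs$J,
                       matched_fraction = round(pairs$matched_fraction, 3L))
  idx_matched <- c(pairs$pairs$treated_id, pairs$pairs$control_id)
  cov_means <- do.call(rbind, lapply(covariates, function(v) {
    data.frame(covariate = v,
               initial_mean = mean(data[[v]], na.rm = TRUE),
               matched_mean = if (length(idx_matched)) {
                 mean(data[[v]][idx_matched], na.rm = TRUE)
               } else NA_real_)
  }))
  structure(list(counts = counts, covariate_means = cov_means),
            class = "matching_summary")
}

#' @export
print.matching_summary <- function(x, ...) {
  cat("Matching diagnostics\n")
  print(x$counts, row.names = FALSE)
  cat("\nCovariate means (initial vs matched sample)\n")
  print(x$covariate_means, row.names = FALSE, digits = 3L)
  invisible(x)
}
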