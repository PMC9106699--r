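#' Within-pair outcome differences
#'
#' For each matched pair, the treated-minus-control difference in the
#' outcome at a given day offset (0 = the matched day itself, -1 the
#' previous day — the negative-control outcome — and +1 the following
#' day). Pairs in which either member's value is missing at that offset
#' are dropped listwise; the number dropped is attached as an attribute.
#'
#' @param data the `daily_dataset` the design was built on.
#' @param pairs a `matched_design`.
#' @param outcome outcome column name (e.g. `"pm10"`).
#' @param offset integer day offset.
#' @return Numeric vector of differences (attribute `n_dropped`).
#' @export
pair_differences <- function(data, pairs, outcome, offset = 0L) {
  stopifnot(inherits(pairs, "matched_design"))
  if (pairs$J == 0L) stop("no matched pairs")
  col <- offset_col(outcome, as.integer(offset))
  data <- .ensure_offset_cols(data, col)
  if (!col %in% names(data)) stop("unknown outcome: ", outcome)
  y_t <- data[[col]][pairs$pairs$treated_id]
  y_c <- data[[col]][pairs$pairs$control_id]
  keep <- !is.na(y_t) & !is.na(y_c)
  if (!any(keep)) {
    stop("no pairs with complete '", col, "' values")
  }
  structure(y_t[keep] - y_c[keep], n_dropped = sum(!keep))
}

#' Neymanian estimate from matched-pair differences
#'
#' The point estimate is the mean of the observed pair differences; the
#' variance estimate is the conservative
#' `sum((d_j - tau_hat)^2) / (J (J - 1))`, whose expectation is at least
#' the true sampling variance and exactly equals it under a constant
#' treatment effect. Confidence intervals use the Gaussian approximation
#' with the conventional multipliers 1.96 (95%) and 2.576 (99%).
#'
#' @param diffs numeric vector of pair differences (J >= 2).
#' @param z95,z99 normal multipliers of the two interval levels.
#' @param outcome,offset optional labels carried into the result.
#' @param control_mean optional matched control-arm mean used to express
#'   the estimate as a relative increase.
#' @return An `effect_estimate`: `J`, `tau_hat`, `var_hat`, `se`, `ci95`,
#'   `ci99`, and `relative_increase` (percent, when `control_mean` given).
#' @export
neyman_estimate <- function(diffs, z95 = 1.96, z99 = 2.576,
                            outcome = NA_character_, offset = NA_integer_,
                            control_mean = NULL) {
  diffs <- as.numeric(diffs)
  J <- length(diffs)
  if (J < 2L) stop("at least 2 pair differences are needed")
  tau_hat <- mean(diffs)
  var_hat <- sum((diffs - tau_hat)^2) / (J * (J - 1))
  se <- sqrt(var_hat)
  out <- list(outcome = outcome, offset = offset, J = J,
              tau_hat = tau_hat, var_hat = var_hat, se = se,
              ci95 = c(tau_hat - z95 * se, tau_hat + z95 * se),
              ci99 = c(tau_hat - z99 * se, tau_hat + z99 * se),
              relative_increase = if (!is.null(control_mean) &&
                                      is.finite(control_mean) &&
                                      control_mean != 0) {
                100 * tau_hat / control_mean
              } else NA_real_)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, digits = 3L, ...) {
  lab <- if (!is.na(x$outcome)) {
    paste0(x$outcome, if (!is.na(x$offset) && x$offset != 0L) {
      sprintf(" (day %+d)", x$offset)
    } else "")
  } else "effect"
  cat(sprintf("%s: tau_hat = %s ug/m3 (J = %d pairs)\n", lab,
              format(x$tau_hat, digits = digits), x$J))
  cat(sprintf("  95%% CI (%s, %s); 99%% CI (%s, %s); SE %s\n",
              format(x$ci95[1L], digits = digits),
              format(x$ci95[2L], digits = digits),
              format(x$ci99[1L], digits = digits),
              format(x$ci99[2L], digits = digits),
              format(x$se, digits = digits)))
  if (is.finite(x$relative_increase)) {
    cat(sprintf("  relative increase: %s%% of the matched control mean\n",
                format(x$relative_increase, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.effect_estimate <- function(object, ...) {
  c(tau_hat = object$tau_hat)
}

#' @export
confint.effect_estimate <- function(object, parm, level = 0.95, ...) {
  ci <- if (level >= 0.99) object$ci99 else object$ci95
  matrix(ci, nrow = 1L,
         dimnames = list("tau_hat",
                         paste0(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2), " %")))
}

#' Effects on the previous, current and following days
#'
#' One Neymanian estimate per outcome and day offset. The offset -1
#' column doubles as the negative-control outcome: North-East wind today
#' cannot causally change yesterday's concentrations, so a clearly
#' non-zero estimate there signals residual (hidden) bias. The relative
#' increase is expressed against the matched control-arm mean at the same
#' offset.
#'
#' @inheritParams pair_differences
#' @param outcomes character vector of outcome names.
#' @param offsets integer day offsets.
#' @return An `effect_table` data frame (one row per outcome x offset).
#' @export
lead_lag_effects <- function(data, pairs, outcomes = c("no2", "o3", "pm10",
                                                       "pm2_5"),
                             offsets = c(-1L, 0L, 1L)) {
  cols <- unlist(lapply(outcomes, function(o) {
    vapply(offsets, function(k) offset_col(o, as.integer(k)), character(1L))
  }))
  data <- .ensure_offset_cols(data, cols)
  rows <- list()
  for (o in outcomes) {
    for (k in as.integer(offsets)) {
      d <- pair_differences(data, pairs, o, k)
      cm <- mean(data[[offset_col(o, k)]][pairs$pairs$control_id],
                 na.rm = TRUE)
      est <- neyman_estimate(d, outcome = o, offset = k, control_mean = cm)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = o, offset = k, J = est$J, n_dropped = attr(d, "n_dropped"),
        tau_hat = est$tau_hat, se = est$se,
        ci95_low = est$ci95[1L], ci95_high = est$ci95[2L],
        ci99_low = est$ci99[1L], ci99_high = est$ci99[2L],
        relative_increase = est$relative_increase)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @export
print.effect_table <- function(x, digits = 3L, ...) {
  cat("Neymanian estimates by outcome and day offset (ug/m3)\n")
  print.data.frame(x, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Precision of the pairwise versus a completely randomized design
#'
#' Compares the estimated sampling variance of the matched pairwise
#' experiment with what a completely randomized experiment on the same
#' matched days would give: `s_t^2 / J + s_c^2 / J`, with `s_t^2`, `s_c^2`
#' the sample variances of the matched treated and control outcome values.
#' A precision ratio above 1 means pairing helped.
#'
#' @inheritParams pair_differences
#' @return List with `var_complete`, `se_complete`, `se_pairwise` and
#'   `precision_ratio` (= `se_complete / se_pairwise`).
#' @export
complete_randomization_variance <- function(data, pairs, outcome,
                                            offset = 0L) {
  col <- offset_col(outcome, as.integer(offset))
  data <- .ensure_offset_cols(data, col)
  y_t <- data[[col]][pairs$pairs$treated_id]
  y_c <- data[[col]][pairs$pairs$control_id]
  keep <- !is.na(y_t) & !is.na(y_c)
  y_t <- y_t[keep]
  y_c <- y_c[keep]
  J <- sum(keep)
  if (J < 2L) stop("at least 2 complete pairs are needed")
  var_complete <- stats::var(y_t) / J + stats::var(y_c) / J
  est <- neyman_estimate(y_t - y_c)
  list(var_complete = var_complete,
       se_complete = sqrt(var_complete),
       se_pairwise = est$se,
       precision_ratio = sqrt(var_complete) / est$se)
}
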