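#' Absolute standardized mean difference
#'
#' `|mean(values_t) - mean(values_c)| / sd_ref`. The reference standard
#' deviation is supplied by the caller so that before- and after-matching
#' comparisons can share the same denominator; [balance_table()] uses the
#' pooled pre-match standard deviation. Values above 0.1 are conventionally
#' read as imbalance.
#'
#' @param values_t,values_c treated and control samples (missing values
#'   dropped).
#' @param sd_ref positive reference standard deviation.
#' @return Non-negative scalar.
#' @export
std_mean_diff <- function(values_t, values_c, sd_ref) {
  stopifnot(length(values_t) > 0, length(values_c) > 0)
  if (!is.finite(sd_ref) || sd_ref <= 0) {
    stop("sd_ref must be a positive number")
  }
  abs(mean(values_t, na.rm = TRUE) - mean(values_c, na.rm = TRUE)) / sd_ref
}

#' Per-level percentage-point differences for a categorical covariate
#'
#' For each level observed in either group, the absolute difference in
#' group shares expressed in percentage points; levels absent from one
#' group count as share 0 there.
#'
#' @param values_t,values_c treated and control samples (missing values
#'   dropped).
#' @return List with `levels` (data frame of level, share_t, share_c,
#'   `diff_pp`) and `mean_diff_pp`, the mean absolute difference across
#'   levels.
#' @export
categorical_diff <- function(values_t, values_c) {
  values_t <- values_t[!is.na(values_t)]
  values_c <- values_c[!is.na(values_c)]
  stopifnot(length(values_t) > 0, length(values_c) > 0)
  lev <- sort(unique(c(values_t, values_c)))
  share_t <- vapply(lev, function(l) mean(values_t == l), numeric(1L))
  share_c <- vapply(lev, function(l) mean(values_c == l), numeric(1L))
  levels <- data.frame(level = lev, share_t = share_t, share_c = share_c,
                       diff_pp = abs(share_t - share_c) * 100)
  list(levels = levels, mean_diff_pp = mean(levels$diff_pp))
}

.default_continuous <- c("temperature", "wind_speed", "humidity",
                         "pm10_lag1")
.default_categorical <- c("weekend", "holiday", "bank_day", "rainfall_cat")

#' Covariate balance before and after matching
#'
#' Quantifies how far the design stage brings treated and control days
#' towards exchangeability. Continuous covariates are summarised by the
#' absolute standardized mean difference, with the pooled standard
#' deviation of the full pre-match sample as the denominator for both
#' stages so they are directly comparable; categorical covariates by the
#' mean absolute percentage-point difference across levels. The "before"
#' rows compare all treated to all control days (optionally within
#' calendar months, the comparison that motivates matching), the "after"
#' rows compare the matched treated to the matched control days.
#'
#' @param data a `daily_dataset`.
#' @param pairs a `matched_design` built on `data` (or `NULL` for a
#'   before-only table).
#' @param continuous,categorical covariate names; lag columns are derived
#'   when absent.
#' @param by_month also stratify the before-matching comparison by month.
#' @return A `balance_table` data frame with columns `covariate`, `type`,
#'   `stage`, `month` (NA when unstratified), `statistic` and `flag`
#'   (continuous statistic above the 0.1 threshold).
#' @export
balance_table <- function(data, pairs = NULL,
                          continuous = .default_continuous,
                          categorical = .default_categorical,
                          by_month = FALSE) {
  data <- .ensure_offset_cols(data, c(continuous, categorical))
  missing_vars <- setdiff(c(continuous, categorical), names(data))
  if (length(missing_vars)) {
    stop("covariate(s) not in data: ", paste(missing_vars, collapse = ", "))
  }
  t_all <- data$w == 1L
  c_all <- data$w == 0L
  sd_ref <- vapply(continuous, function(v) {
    stats::sd(data[[v]], na.rm = TRUE)
  }, numeric(1L))

  row <- function(v, type, stage, month, stat) {
    data.frame(covariate = v, type = type, stage = stage,
               month = if (is.null(month)) NA_integer_ else month,
               statistic = stat,
               flag = (type == "continuous") & stat > 0.1)
  }
  one_stage <- function(idx_t, idx_c, stage, month = NULL) {
    rows <- lapply(continuous, function(v) {
      row(v, "continuous", stage, month,
          std_mean_diff(data[[v]][idx_t], data[[v]][idx_c], sd_ref[[v]]))
    })
    rows <- c(rows, lapply(categorical, function(v) {
      row(v, "categorical", stage, month,
          categorical_diff(data[[v]][idx_t], data[[v]][idx_c])$mean_diff_pp)
    }))
    do.call(rbind, rows)
  }

  out <- one_stage(which(t_all), which(c_all), "before")
  if (by_month) {
    for (m in sort(unique(data$month))) {
      in_m <- data$month == m
      if (any(t_all & in_m) && any(c_all & in_m)) {
        out <- rbind(out, one_stage(which(t_all & in_m),
                                    which(c_all & in_m), "before", m))
      }
    }
  }
  if (!is.null(pairs)) {
    stopifnot(inherits(pairs, "matched_design"))
    if (pairs$J == 0L) {
      warning("empty matched set: after-matching rows omitted")
    } else {
      out <- rbind(out, one_stage(pairs$pairs$treated_id,
                                  pairs$pairs$control_id, "after"))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("balance_table", "data.frame")
  out
}

#' @export
print.balance_table <- function(x, digits = 3L, ...) {
  cat("Covariate balance (continuous: |SMD|; categorical: mean pp diff)\n")
  print.data.frame(x, row.names = FALSE, digits = digits)
  overall <- x[is.na(x$month), , drop = FALSE]
  for (stage in unique(overall$stage)) {
    sub <- overall[overall$stage == stage, , drop = FALSE]
    cat(sprintf("mean %s: continuous SMD %.3f, categorical %.1f pp\n",
                stage,
                mean(sub$statistic[sub$type == "continuous"]),
                mean(sub$statistic[sub$type == "categorical"])))
  }
  invisible(x)
}

#' @rdname balance_table
#' @param object,x a `matched_design`.
#' @param ... passed on.
#' @export
summary.matched_design <- function(object, ...) {
  list(diagnostics = matching_summary(object$data, object),
       balance = balance_table(object$data, object, ...))
}

#' Love plot of covariate balance
#'
#' Dot chart of the balance statistics before (open circles) and after
#' (filled) matching, with the conventional 0.1 threshold drawn for the
#' continuous panel.
#'
#' @export
#' @rdname balance_table
plot.matched_design <- function(x, ...) {
  tab <- balance_table(x$data, x, ...)
  tab <- tab[is.na(tab$month), , drop = FALSE]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  for (type in c("continuous", "categorical")) {
    sub <- tab[tab$type == type, , drop = FALSE]
    covs <- unique(sub$covariate)
    xlim <- range(0, sub$statistic)
    graphics::plot(NA, xlim = xlim, ylim = c(0.5, length(covs) + 0.5),
                   yaxt = "n", xlab = if (type == "continuous") {
                     "|standardized mean difference|"
                   } else "mean difference (pp)",
                   ylab = "", main = type)
    graphics::axis(2, at = seq_along(covs), labels = covs, las = 1)
    if (type == "continuous") {
      graphics::abline(v = 0.1, lty = 2, col = "grey40")
    }
    for (i in seq_along(covs)) {
      b <- sub$statistic[sub$covariate == covs[i] & sub$stage == "before"]
      a <- sub$statistic[sub$covariate == covs[i] & sub$stage == "after"]
      graphics::points(b, i, pch = 1)
      if (length(a)) graphics::points(a, i, pch = 19)
    }
  }
  invisible(x)
}
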