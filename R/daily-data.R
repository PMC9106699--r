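#' Canonical column names of a daily dataset
#'
#' @description
#' A daily dataset is a data frame with one row per calendar day. The
#' canonical columns are: `date`, the pollutant concentrations (`no2`, `o3`,
#' `pm10`, `pm2_5`, in ug/m3), the weather covariates (`temperature` in
#' degrees C, `wind_speed` in m/s, `wind_direction` in degrees on a 360
#' compass rose, `humidity` in percent, `rainfall_cat` an ordinal category
#' 1-4), and the calendar indicators `holiday` and `bank_day` (0/1).
#' `weekend`, `month`, `year`, `julian` (integer day index from the first
#' date) and the treatment indicator `w` are derived automatically.
#'
#' @keywords internal
#' @name daily-schema
NULL

.pollutants <- c("no2", "o3", "pm10", "pm2_5")

.required_cols <- c("date", "temperature", "wind_speed", "wind_direction",
                    "humidity", "rainfall_cat", "holiday", "bank_day")

#' Validate a data frame and derive the daily-dataset fields
#'
#' Checks ranges and date ordering, derives `julian`, `weekend`, `month`,
#' `year` and the treatment indicator `w` from the wind-direction sector,
#' and returns a `daily_dataset` (a data frame subclass).
#'
#' @param df data frame holding the canonical columns (see [daily-schema]).
#' @param sector numeric length-2, the North-East wind sector in degrees
#'   (closed interval); days whose wind direction falls inside it are
#'   treated (`w = 1`).
#' @return A `daily_dataset` data frame.
#' @export
as_daily_dataset <- function(df, sector = c(10, 90)) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in rows ",
                           paste(which(is.na(df$date)), collapse = ", "))
  if (anyDuplicated(df$date)) {
    stop("duplicate dates in rows ",
         paste(which(duplicated(df$date)), collapse = ", "))
  }
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL

  bad_row <- function(ok, what) {
    bad <- which(!ok)   # NA counts as ok: missing values are preserved
    if (length(bad)) {
      stop(what, " out of range in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (date ", df$date[bad[1L]], ")")
    }
  }
  wd <- df$wind_direction
  bad_row(is.na(wd) | (wd >= 0 & wd < 360), "wind_direction")
  bad_row(is.na(df$humidity) | (df$humidity >= 0 & df$humidity <= 100),
          "humidity")
  bad_row(is.na(df$rainfall_cat) | df$rainfall_cat %in% 1:4, "rainfall_cat")

  df$julian  <- as.integer(df$date - df$date[1L])
  df$weekend <- as.integer(format(df$date, "%u") %in% c("6", "7"))
  df$month   <- as.integer(format(df$date, "%m"))
  df$year    <- as.integer(format(df$date, "%Y"))
  df$w       <- assign_treatment(df$wind_direction, sector)

  attr(df, "sector") <- sector
  class(df) <- c("daily_dataset", "data.frame")
  df
}

#' Read a daily dataset from CSV
#'
#' Reads a one-row-per-day CSV, optionally renaming columns via `schema`,
#' validates it and derives the calendar fields and the treatment
#' indicator. Missing cells may be empty or `NA`.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(pm10 = "PM10", temperature = "t_mean")`. Unmapped canonical names
#'   are looked up directly.
#' @inheritParams as_daily_dataset
#' @return A `daily_dataset` data frame.
#' @seealso [write_daily_dataset()]
#' @export
read_daily_dataset <- function(path, schema = NULL, sector = c(10, 90)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!is.null(schema)) {
    stopifnot(!is.null(names(schema)))
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) stop("schema column not in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  as_daily_dataset(df, sector = sector)
}

#' Write a daily dataset to CSV
#'
#' Writes the dataset with its canonical schema; imputation flag columns
#' (`imputed_<var>`), if present, are kept.
#'
#' @param data a `daily_dataset`.
#' @param path output CSV path.
#' @export
write_daily_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.daily_dataset <- function(x, ...) {
  cat("Daily dataset: ", nrow(x), " days (", format(x$date[1L]), " to ",
      format(x$date[nrow(x)]), ")\n", sep = "")
  sector <- attr(x, "sector")
  cat("Treatment: wind direction in [", sector[1L], ", ", sector[2L],
      "] degrees; ", sum(x$w), " treated, ", sum(1 - x$w), " control\n",
      sep = "")
  invisible(x)
}

#' Trimmed-mean aggregation of hourly readings to a daily value
#'
#' Computes the daily concentration as a trimmed mean of the (pooled
#' station-) hourly values: the non-missing values are sorted and
#' `floor(n * trim_frac)` observations are dropped from each tail before
#' averaging. If more than `max_missing` hourly readings are missing the
#' daily value is set to missing.
#'
#' With 24 hourly values and the default 2.5% trim nothing is dropped
#' (`floor(24 * 0.025) = 0`); the trim becomes active when several
#' stations' hours are pooled.
#'
#' @param hourly_values numeric vector of hourly concentrations, `NA` for
#'   missing readings.
#' @param trim_frac proportion trimmed from each tail, in `[0, 0.5)`.
#' @param max_missing maximum number of missing readings tolerated before
#'   the day is declared missing.
#' @return A single concentration, or `NA` if too many readings are missing.
#' @export
aggregate_hourly_to_daily <- function(hourly_values, trim_frac = 0.025,
                                      max_missing = 3L) {
  stopifnot(length(hourly_values) > 0, trim_frac >= 0, trim_frac < 0.5)
  if (sum(is.na(hourly_values)) > max_missing) return(NA_real_)
  v <- sort(hourly_values[!is.na(hourly_values)])
  if (!length(v)) return(NA_real_)
  k <- floor(length(v) * trim_frac)
  if (k > 0) v <- v[(k + 1L):(length(v) - k)]
  mean(v)
}

#' Treatment assignment from wind direction
#'
#' A day is treated (`1`) when the wind blows from the North-East, i.e.
#' its direction lies in the closed sector `[sector[1], sector[2]]`
#' degrees, and control (`0`) otherwise.
#'
#' @param wind_direction degrees in `[0, 360)`; vectorised.
#' @param sector closed angular interval in degrees. A sector wrapping
#'   through North (first endpoint larger than the second) is supported.
#' @return Integer vector of 0/1 (NA where the direction is missing).
#' @export
assign_treatment <- function(wind_direction, sector = c(10, 90)) {
  stopifnot(length(sector) == 2L)
  ok <- is.na(wind_direction) | (wind_direction >= 0 & wind_direction < 360)
  if (!all(ok)) stop("wind_direction outside [0, 360) at position(s) ",
                     paste(utils::head(which(!ok), 5L), collapse = ", "))
  inside <- if (sector[1L] <= sector[2L]) {
    wind_direction >= sector[1L] & wind_direction <= sector[2L]
  } else {
    wind_direction >= sector[1L] | wind_direction <= sector[2L]
  }
  as.integer(inside)
}

#' Add lagged and lead columns
#'
#' For each requested variable and offset, adds a column `<var>_lag<k>`
#' (offset -k) or `<var>_lead<k>` (offset +k) holding the variable's value
#' on the calendar day `date + offset`. Lags are calendar-based: across a
#' gap in the date sequence the lag is missing rather than the previous
#' row's value, because the matching constraints refer to the true
#' previous day.
#'
#' @param data a `daily_dataset` (or plain data frame with a `date` column).
#' @param variables character vector of column names.
#' @param offsets integer offsets; negative are lags, positive leads.
#' @return `data` with the extra columns.
#' @export
add_lags_and_leads <- function(data, variables, offsets = c(-1L, 1L)) {
  stopifnot(is.data.frame(data), "date" %in% names(data))
  unknown <- setdiff(variables, names(data))
  if (length(unknown)) stop("unknown variable(s): ",
                            paste(unknown, collapse = ", "))
  offsets <- as.integer(offsets)
  stopifnot(all(is.finite(offsets)))
  for (v in variables) {
    for (k in offsets) {
      if (k == 0L) next
      idx <- match(data$date + k, data$date)
      data[[offset_col(v, k)]] <- data[[v]][idx]
    }
  }
  data
}

# column name for variable v at day offset k (k = 0 is the variable itself)
offset_col <- function(v, k) {
  if (k == 0L) v
  else if (k < 0L) paste0(v, "_lag", -k)
  else paste0(v, "_lead", k)
}
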