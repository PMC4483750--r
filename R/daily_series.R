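#' Daily concentration series
#'
#' The universal input type of the package: a sequence of strictly positive
#' concentration observations (conventionally 24-h means in µg/m³) on
#' strictly increasing calendar dates. By default dates must be consecutive
#' calendar days; `allow_gaps = TRUE` accepts gapped records and the
#' forecasters then treat observations as equally spaced by position.
#'
#' Positivity is enforced at construction because two of the error indexes
#' (MPE and the Theil coefficient) divide by the observed values.
#'
#' @param dates A `Date` vector (or values coercible via `as.Date()`).
#' @param values Numeric vector of strictly positive concentrations, one per
#'   date.
#' @param allow_gaps Accept non-consecutive (but still strictly increasing)
#'   dates?
#' @return An object of class `daily_series`: a data frame with columns
#'   `date` and `value`.
#' @examples
#' daily_series(as.Date("2015-01-22") + 0:2, c(58.2, 64.4, 73.6))
#' @export
daily_series <- function(dates, values, allow_gaps = FALSE) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values)) {
    stopf("lengths differ: %d dates vs %d values", length(dates), length(values))
  }
  if (length(dates) < 1L) stopf("a daily_series needs at least one observation")
  if (anyNA(dates)) stopf("unparseable date at row %d", which(is.na(dates))[1L])
  if (anyNA(values) || any(!is.finite(values))) {
    stopf("non-numeric or non-finite value at row %d",
          which(!is.finite(values))[1L])
  }
  if (any(values <= 0)) {
    stopf("non-positive value (%g) at row %d: concentrations must be > 0",
          values[which(values <= 0)[1L]], which(values <= 0)[1L])
  }
  d <- as.numeric(diff(dates))
  if (any(d == 0)) {
    stopf("duplicate date %s", format(dates[which(d == 0)[1L]]))
  }
  if (any(d < 0)) stopf("dates must be strictly increasing")
  if (!allow_gaps && any(d != 1)) {
    i <- which(d != 1)[1L]
    stopf("gap in calendar dates between %s and %s; use allow_gaps = TRUE to accept",
          format(dates[i]), format(dates[i + 1L]))
  }
  structure(data.frame(date = dates, value = values),
            class = c("daily_series", "data.frame"))
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series: %d days, %s to %s>\n", nrow(x),
              format(x$date[1L]), format(x$date[nrow(x)])))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

parse_dates <- function(x) {
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  slash <- is.na(out)
  if (any(slash)) out[slash] <- as.Date(x[slash], format = "%Y/%m/%d")
  out
}

#' Read a daily series from CSV
#'
#' Reads a headered CSV with a date column (ISO `2015-01-22` or slash
#' `2015/1/22` format) and a strictly positive numeric value column, sorts
#' rows by date and validates the [daily_series] invariants. Offending rows
#' (non-positive values, duplicate dates) are reported by row index.
#'
#' @param path Path to a CSV file.
#' @param date_column,value_column Column names (defaults `"date"`,
#'   `"value"`).
#' @param allow_gaps Passed to [daily_series()].
#' @return A [daily_series].
#' @export
read_series <- function(path, date_column = "date", value_column = "value",
                        allow_gaps = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(date_column, value_column)) {
    if (!col %in% names(raw)) stopf("column '%s' not found in %s", col, path)
  }
  dates <- parse_dates(raw[[date_column]])
  if (anyNA(dates)) stopf("unparseable date '%s' at row %d",
                          raw[[date_column]][which(is.na(dates))[1L]],
                          which(is.na(dates))[1L])
  values <- suppressWarnings(as.numeric(raw[[value_column]]))
  if (anyNA(values)) stopf("non-numeric value '%s' at row %d",
                           raw[[value_column]][which(is.na(values))[1L]],
                           which(is.na(values))[1L])
  bad <- which(values <= 0)
  if (length(bad)) stopf("non-positive value (%g) at row %d", values[bad[1L]], bad[1L])
  o <- order(dates)
  daily_series(dates[o], values[o], allow_gaps = allow_gaps)
}

#' Write a daily series to CSV
#'
#' Values are written with full double precision so that
#' `read_series(write_series(x))` restores them exactly.
#'
#' @param series A [daily_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  df <- data.frame(date = format(series$date, "%Y-%m-%d"),
                   value = sprintf("%.17g", series$value))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monthly means of a daily series
#'
#' Arithmetic mean of the daily values within each calendar month present in
#' the series, the standard first look at the seasonal (winter-high,
#' summer-low) structure of PM2.5 records.
#'
#' @param series A [daily_series].
#' @return A data frame with columns `year`, `month`, `mean_value`, `n_days`,
#'   one row per calendar month present, in chronological order.
#' @export
monthly_means <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  key <- format(series$date, "%Y-%m")
  agg <- lapply(split(series$value, key), function(v) c(mean(v), length(v)))
  keys <- sort(names(agg))
  data.frame(
    year = as.integer(substr(keys, 1, 4)),
    month = as.integer(substr(keys, 6, 7)),
    mean_value = vapply(agg[keys], `[`, numeric(1), 1L),
    n_days = as.integer(vapply(agg[keys], `[`, numeric(1), 2L)),
    row.names = NULL
  )
}

#' Split a daily series into training and holdout windows
#'
#' The final `n_holdout` observations form the evaluation window (mirroring
#' a next-`n`-days prediction design); everything before them is the
#' training window. Concatenating the two restores the input.
#'
#' @param series A [daily_series].
#' @param n_holdout Number of trailing observations to hold out;
#'   `0 < n_holdout < length(series)`.
#' @return A list with components `train` and `test`, both [daily_series].
#' @export
split_holdout <- function(series, n_holdout) {
  stopifnot(inherits(series, "daily_series"))
  n <- nrow(series)
  n_holdout <- as.integer(n_holdout)
  if (n_holdout < 1L || n_holdout >= n) {
    stopf("n_holdout must satisfy 0 < n_holdout < %d (got %d)", n, n_holdout)
  }
  idx <- seq_len(n - n_holdout)
  list(
    train = daily_series(series$date[idx], series$value[idx], allow_gaps = TRUE),
    test = daily_series(series$date[-idx], series$value[-idx], allow_gaps = TRUE)
  )
}
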