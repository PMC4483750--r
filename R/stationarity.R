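# Augmented Dickey-Fuller unit-root test (constant, no deterministic trend)
# and the differencing-order suggestion built on it.

# Finite-sample quantiles of the Dickey-Fuller tau_mu statistic (regression
# with an intercept only), Fuller (1976, Table 8.5.2). Rows: sample size;
# columns: lower and upper tail probabilities used for p-value interpolation.
adf_tau_mu_table <- function() {
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  tab <- rbind(
    `25`  = c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    `50`  = c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    `100` = c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    `250` = c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    `500` = c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    `Inf` = c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  )
  list(n = c(25, 50, 100, 250, 500, Inf), probs = probs, quantiles = tab)
}

#' Augmented Dickey-Fuller test (intercept, no trend)
#'
#' Tests the null hypothesis that `x` has a unit root against the
#' alternative of (level-)stationarity, using the regression of the first
#' difference on the lagged level, an intercept and `lags` lagged
#' differences. The t-statistic of the lagged level is compared with the
#' Dickey-Fuller \eqn{\tau_\mu} finite-sample table; the p-value is
#' interpolated over both the table's tail probabilities and sample size,
#' and clamped to [0.01, 0.99].
#'
#' No deterministic trend term is included: a trending series therefore
#' tests non-stationary, which is exactly the behaviour wanted when the
#' test drives the choice of differencing order (a linear trend suggests
#' one difference, a quadratic trend two).
#'
#' @param x Numeric vector, length >= 10 after lagging.
#' @param lags Number of lagged differences; default
#'   `trunc((length(x) - 1)^(1/3))`.
#' @return A list with `statistic`, `p_value`, `lags`.
#' @export
adf_test <- function(x, lags = trunc((length(x) - 1)^(1 / 3))) {
  x <- as.numeric(x)
  lags <- max(0L, as.integer(lags))
  n <- length(x)
  if (n - lags - 1L < 10L) stopf("series too short for an ADF test with %d lags", lags)
  if (stats::var(x) == 0) {
    # a constant has no unit root; report the strongest possible rejection
    return(list(statistic = -Inf, p_value = 0.01, lags = lags))
  }
  dx <- diff(x)
  t_idx <- (lags + 1L):(n - 1L)
  y <- dx[t_idx]
  level <- x[t_idx]
  if (lags > 0L) {
    lagged <- sapply(seq_len(lags), function(k) dx[t_idx - k])
    fit <- stats::lm(y ~ level + lagged)
  } else {
    fit <- stats::lm(y ~ level)
  }
  sm <- summary(fit)$coefficients
  stat <- sm["level", "t value"]

  tab <- adf_tau_mu_table()
  nobs <- length(y)
  if (nobs > 500) {
    qrow <- tab$quantiles["Inf", ]
  } else {
    fin <- is.finite(tab$n)
    # quantile row for this sample size, interpolated column-wise over n
    qrow <- apply(tab$quantiles[fin, ], 2, function(q) {
      stats::approx(tab$n[fin], q, xout = nobs, rule = 2)$y
    })
  }
  p <- stats::approx(qrow, tab$probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = unname(p), lags = lags)
}

#' Stationarity check and differencing-order suggestion
#'
#' Applies the ADF unit-root test ([adf_test()]) to the series and, if the
#' null of a unit root is not rejected, to its successive differences,
#' returning the smallest differencing order `d <= max_d` whose `d`-th
#' difference tests stationary. In routine practice `d` rarely needs to
#' exceed 2, so `max_d` defaults to (and is capped at) 2.
#'
#' @param series A [daily_series] or numeric vector, length >= 20.
#' @param significance Test level for the unit-root decision (default 0.05).
#' @param max_d Maximum differencing order considered (default 2).
#' @return A list with `stationary` (is the undifferenced series
#'   stationary?), `suggested_d`, and `p_values` (one per tried order).
#'   If no order up to `max_d` passes, `suggested_d = max_d` with a warning.
#' @export
check_stationarity <- function(series, significance = 0.05, max_d = 2) {
  x <- series_values(series)
  if (length(x) < 20L) stopf("need at least 20 observations (got %d)", length(x))
  stopifnot(significance > 0, significance < 1)
  max_d <- min(as.integer(max_d), 2L)
  p_values <- numeric(0)
  for (d in 0:max_d) {
    xd <- if (d == 0) x else diff(x, differences = d)
    p <- adf_test(xd)$p_value
    p_values <- c(p_values, p)
    if (p < significance) {
      return(list(stationary = d == 0L, suggested_d = d, p_values = p_values))
    }
  }
  warnf("no differencing order up to %d passes the unit-root test; returning d = %d",
        max_d, max_d)
  list(stationary = FALSE, suggested_d = max_d, p_values = p_values)
}
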