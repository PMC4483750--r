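#' Six-index forecast-error report
#'
#' Evaluates a prediction sequence against strictly positive actual
#' observations with the six indexes standardly reported for concentration
#' forecasts:
#' \describe{
#'   \item{MAE}{\eqn{\frac{1}{n}\sum |y_i - \hat y_i|} (µg/m³).}
#'   \item{MPE}{\eqn{\frac{1}{n}\sum |y_i - \hat y_i| / y_i}. Computed with
#'     absolute values, so despite the traditional name it is a mean
#'     absolute percentage error and cannot be negative.}
#'   \item{RMSE}{\eqn{\sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2}} (µg/m³).}
#'   \item{Theil inequality coefficient}{relative-error variant:
#'     \deqn{U = \frac{\sqrt{\frac{1}{n}\sum ((y_i - \hat y_i)/y_i)^2}}
#'                   {\sqrt{\frac{1}{n}\sum \hat y_i^2} +
#'                    \sqrt{\frac{1}{n}\sum y_i^2}}.}
#'     The numerator uses relative errors, not raw errors; the classical
#'     variant with raw errors in the numerator is roughly 40 times larger
#'     on typical PM2.5 levels and is deliberately not computed.}
#'   \item{bias ratio}{\eqn{(\bar y - \bar{\hat y})^2 / \frac{1}{n}\sum (y_i - \hat y_i)^2},
#'     the share of the mean squared error attributable to the gap between
#'     the two means.}
#'   \item{variance ratio}{\eqn{(s_y - s_{\hat y})^2 / \frac{1}{n}\sum (y_i - \hat y_i)^2}
#'     with *population* standard deviations (divisor `n`), the share
#'     attributable to the gap between the two dispersions.}
#' }
#' A perfect prediction gives all six indexes 0 (the two ratios take the
#' convention 0/0 = 0 in that case). MAE never exceeds RMSE.
#'
#' @param actual Actual observations: [daily_series] or strictly positive
#'   numeric vector, length `n >= 2`.
#' @param predicted Predictions: [forecast_result()], [daily_series] or
#'   numeric vector of the same length.
#' @return An object of class `metric_report`: list with `mae`, `mpe`,
#'   `rmse`, `theil_u`, `bias_ratio`, `variance_ratio`, `n`.
#' @examples
#' evaluate_metrics(c(10, 20), c(12, 18))
#' @export
evaluate_metrics <- function(actual, predicted) {
  y <- series_values(actual)
  yh <- if (inherits(predicted, "forecast_result")) predicted$forecasts
        else series_values(predicted)
  n <- length(y)
  if (n != length(yh)) stopf("length mismatch: %d actual vs %d predicted", n, length(yh))
  if (n < 2L) stopf("need at least 2 points")
  if (any(y <= 0)) stopf("actual values must be strictly positive")
  if (any(!is.finite(yh))) stopf("predictions must be finite")

  err <- y - yh
  mse <- mean(err^2)
  if (mse == 0) {
    out <- list(mae = 0, mpe = 0, rmse = 0, theil_u = 0,
                bias_ratio = 0, variance_ratio = 0, n = n)
    return(structure(out, class = "metric_report"))
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- list(
    mae = mean(abs(err)),
    mpe = mean(abs(err) / y),
    rmse = sqrt(mse),
    theil_u = sqrt(mean((err / y)^2)) /
      (sqrt(mean(yh^2)) + sqrt(mean(y^2))),
    bias_ratio = (mean(y) - mean(yh))^2 / mse,
    variance_ratio = (pop_sd(y) - pop_sd(yh))^2 / mse,
    n = n
  )
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metric_report over %d points>\n", x$n))
  cat(sprintf("  MAE  %.*f ug/m3    MPE   %.*f\n", digits, x$mae, digits, x$mpe))
  cat(sprintf("  RMSE %.*f ug/m3    Theil %.*f\n", digits, x$rmse, digits, x$theil_u))
  cat(sprintf("  bias ratio %.*f    variance ratio %.*f\n",
              digits, x$bias_ratio, digits, x$variance_ratio))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(mae = x$mae, mpe = x$mpe, rmse = x$rmse, theil_u = x$theil_u,
             bias_ratio = x$bias_ratio, variance_ratio = x$variance_ratio,
             n = x$n)
}
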