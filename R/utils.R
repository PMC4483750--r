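# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Coerce a daily_series or bare numeric vector to values; used by the
# forecasters, which consume observations by position.
series_values <- function(x) {
  if (inherits(x, "daily_series")) x$value else as.numeric(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Forecast result container
#'
#' A light container shared by all forecasters: the method label, in-sample
#' one-step fitted values aligned to the training index (`NA` where the
#' method had insufficient history), the out-of-sample forecasts and a
#' record of the parameters used.
#'
#' @param method One of `"arima"`, `"ann"`, `"esm"`, `"cfm"`.
#' @param fitted Numeric vector of in-sample one-step predictions, same
#'   length as the training series, `NA`-padded at positions with
#'   insufficient history.
#' @param forecasts Numeric vector of out-of-sample forecasts.
#' @param params Named list recording the parameters behind the forecasts.
#' @return An object of class `forecast_result`.
#' @export
forecast_result <- function(method, fitted, forecasts, params = list()) {
  method <- match.arg(method, c("arima", "ann", "esm", "cfm"))
  forecasts <- as.numeric(forecasts)
  if (length(forecasts) >= 1L && any(!is.finite(forecasts))) {
    stopf("non-finite forecasts produced by method '%s'", method)
  }
  structure(
    list(method = method, fitted = as.numeric(fitted),
         forecasts = forecasts, params = params),
    class = "forecast_result"
  )
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result: %s>\n", x$method))
  cat(sprintf("  fitted: %d values (%d with history)\n",
              length(x$fitted), sum(!is.na(x$fitted))))
  cat(sprintf("  forecasts (h = %d): %s\n", length(x$forecasts),
              paste(signif(utils::head(x$forecasts, 6), 6), collapse = ", ")))
  invisible(x)
}
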