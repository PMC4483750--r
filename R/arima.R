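#' ARIMA model specification
#'
#' Records an ARIMA(p, d, q) model
#' \deqn{\varphi_p(B) W_t = \theta_q(B) \varepsilon_t, \quad
#'       W_t = (1 - B)^d Y_t,}
#' with \eqn{\varphi_p(B) = 1 - \varphi_1 B - \dots - \varphi_p B^p} and
#' \eqn{\theta_q(B) = 1 - \theta_1 B - \dots - \theta_q B^q}. Note the
#' subtraction convention for the moving-average polynomial: the stored
#' `theta` are the *negatives* of the MA coefficients reported by
#' [stats::arima()], which uses \eqn{1 + \theta_1 B + \dots}. The package
#' uses the subtraction convention everywhere ([fit_arima()] converts).
#'
#' @param p,d,q Non-negative integer orders; `d <= 2` (higher differencing
#'   orders are rarely justified for concentration series and are rejected).
#' @param phi AR coefficients, length `p`.
#' @param theta MA coefficients in the subtraction convention, length `q`.
#' @param mean Mean of the (differenced, if `d > 0`) process; forecasts of
#'   an ARIMA(0, 0, 0) model are this value at every step.
#' @param sigma2 Innovation variance (optional, recorded for reporting).
#' @return An object of class `arima_spec`.
#' @examples
#' arima_spec(1, 0, 0, phi = 0.5)  # AR(1)
#' @export
arima_spec <- function(p, d, q, phi = numeric(0), theta = numeric(0),
                       mean = 0, sigma2 = NA_real_) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  if (p < 0L || d < 0L || q < 0L) stopf("orders must be non-negative")
  if (d > 2L) stopf("d = %d: differencing order above 2 is not supported", d)
  if (length(phi) != p) stopf("phi must have length p = %d", p)
  if (length(theta) != q) stopf("theta must have length q = %d", q)
  structure(
    list(p = p, d = d, q = q, phi = as.numeric(phi),
         theta = as.numeric(theta), mean = mean, sigma2 = sigma2),
    class = "arima_spec"
  )
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("<arima_spec (%d,%d,%d)> mean %.4g", x$p, x$d, x$q, x$mean))
  if (x$p) cat("  phi:", paste(signif(x$phi, 5), collapse = " "))
  if (x$q) cat("  theta:", paste(signif(x$theta, 5), collapse = " "))
  cat("\n")
  invisible(x)
}

polyroot_ok <- function(coefs) {
  # roots of 1 - c1 z - c2 z^2 - ... outside the unit circle
  if (!length(coefs)) return(TRUE)
  all(Mod(polyroot(c(1, -coefs))) > 1)
}

#' Select an ARIMA order by information-criterion grid search
#'
#' Chooses the differencing order by the unit-root test
#' ([check_stationarity()]), then minimises an information criterion over
#' the (p, q) grid. BIC is the default: its stronger penalty makes the
#' selection consistent, so a white-noise series is almost always assigned
#' order (0, 0, 0), where AIC's fixed penalty of 2 per parameter overfits a
#' sizeable fraction of the time. Candidate models are fitted by
#' conditional sum-of-squares for speed; ties are broken toward the
#' smaller model (then smaller p), so the result is deterministic.
#'
#' @param series A [daily_series] or numeric vector, length
#'   `> max_p + max_q + 10`.
#' @param max_p,max_q Grid bounds (defaults 5, 5).
#' @param max_d Maximum differencing order passed to
#'   [check_stationarity()] (default 2).
#' @param ic `"bic"` (default) or `"aic"`.
#' @param significance Level for the unit-root test (default 0.05).
#' @param fixed Optional length-3 integer vector `(p, d, q)`; when given,
#'   selection is disabled and the order is returned verbatim (used to pin
#'   an externally chosen order such as ARMA(2, 3)).
#' @return A list with `p`, `d`, `q`, the `ic` used, and `ic_value`.
#' @export
select_order <- function(series, max_p = 5, max_q = 5, max_d = 2,
                         ic = c("bic", "aic"), significance = 0.05,
                         fixed = NULL) {
  ic <- match.arg(ic)
  if (!is.null(fixed)) {
    stopifnot(length(fixed) == 3L)
    return(list(p = as.integer(fixed[1L]), d = as.integer(fixed[2L]),
                q = as.integer(fixed[3L]), ic = "fixed", ic_value = NA_real_))
  }
  x <- series_values(series)
  max_p <- as.integer(max_p); max_q <- as.integer(max_q)
  if (max_p < 0L || max_q < 0L) stopf("empty order grid")
  if (length(x) <= max_p + max_q + 10L) {
    stopf("series too short (%d) for a (%d, %d) grid", length(x), max_p, max_q)
  }
  d <- check_stationarity(x, significance = significance, max_d = max_d)$suggested_d

  best <- NULL
  for (p in 0:max_p) for (q in 0:max_q) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(x, order = c(p, d, q), method = "CSS",
                                    include.mean = (d == 0L))),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$loglik)) next
    k <- length(fit$coef) + 1  # + innovation variance
    val <- -2 * fit$loglik + if (ic == "aic") 2 * k else log(fit$nobs) * k
    if (is.null(best) || val < best$ic_value - 1e-10 ||
        (abs(val - best$ic_value) <= 1e-10 &&
         (p + q < best$p + best$q || (p + q == best$p + best$q && p < best$p)))) {
      best <- list(p = p, d = d, q = q, ic = ic, ic_value = val)
    }
  }
  if (is.null(best)) stopf("no candidate model could be estimated")
  best
}

#' Fit an ARIMA model
#'
#' Maximum-likelihood estimation via [stats::arima()] (method `"CSS-ML"`:
#' conditional sum-of-squares start values, then exact Gaussian likelihood;
#' the method is recorded in the returned parameters). After estimation the
#' residuals are checked for remaining autocorrelation with a Ljung-Box
#' portmanteau test at lag `min(10, n/5)`; a p-value below 0.05 raises a
#' warning (the model is then not an adequate white-noise-residual fit).
#' Estimated AR or MA polynomials with roots on or inside the unit circle
#' are flagged with a warning as well, never silently returned.
#'
#' @param series A [daily_series] or numeric vector.
#' @param order Length-3 vector `(p, d, q)` or the list returned by
#'   [select_order()].
#' @param method Estimation method for [stats::arima()] (default
#'   `"CSS-ML"`); held fixed across the test suite.
#' @return An object of class `arima_fit`: list with `spec` (an
#'   [arima_spec()] in the subtraction convention), `model` (the underlying
#'   [stats::arima()] fit), `fitted` (one-step in-sample predictions),
#'   `ljung_box` (htest), and `diagnostics`.
#' @export
fit_arima <- function(series, order, method = "CSS-ML") {
  x <- series_values(series)
  if (is.list(order)) order <- c(order$p, order$d, order$q)
  stopifnot(length(order) == 3L)
  p <- as.integer(order[1L]); d <- as.integer(order[2L]); q <- as.integer(order[3L])
  if (d > 2L) stopf("d = %d not supported (must be <= 2)", d)
  if (stats::var(x) == 0) {
    warnf("constant (degenerate) training series: innovation variance is 0")
  }
  fit <- tryCatch(
    stats::arima(x, order = c(p, d, q), method = method, include.mean = (d == 0L)),
    error = function(e) stopf("ARIMA(%d,%d,%d) estimation failed: %s",
                              p, d, q, conditionMessage(e))
  )
  cf <- fit$coef
  phi <- if (p) unname(cf[paste0("ar", seq_len(p))]) else numeric(0)
  # stats::arima uses 1 + theta B + ...; convert to the subtraction convention
  theta <- if (q) -unname(cf[paste0("ma", seq_len(q))]) else numeric(0)
  mu <- if ("intercept" %in% names(cf)) unname(cf[["intercept"]]) else 0
  spec <- arima_spec(p, d, q, phi = phi, theta = theta, mean = mu,
                     sigma2 = fit$sigma2)

  ar_ok <- polyroot_ok(phi)
  ma_ok <- polyroot_ok(theta)
  if (!ar_ok) warnf("estimated AR polynomial is not stationary (root inside unit circle)")
  if (!ma_ok) warnf("estimated MA polynomial is not invertible (root inside unit circle)")

  lb_lag <- max(1L, min(10L, floor(length(x) / 5)))
  lb <- stats::Box.test(stats::residuals(fit), lag = lb_lag, type = "Ljung-Box",
                        fitdf = min(p + q, lb_lag - 1L))
  if (is.finite(lb$p.value) && lb$p.value < 0.05) {
    warnf("Ljung-Box test rejects white-noise residuals (p = %.3g): model may be inadequate",
          lb$p.value)
  }

  structure(
    list(spec = spec, model = fit,
         fitted = as.numeric(x - stats::residuals(fit)),
         values = x, ljung_box = lb,
         diagnostics = list(stationary_ar = ar_ok, invertible_ma = ma_ok,
                            method = method)),
    class = "arima_fit"
  )
}

#' Forecast from an ARIMA model
#'
#' Minimum-mean-square-error forecasts. For a fitted model (`arima_fit`)
#' these come from [stats::predict()] on the underlying fit. For a bare
#' [arima_spec()] plus an explicit history the standard conditional
#' recursion is used: residuals are reconstructed with pre-sample
#' innovations set to zero, future innovations are set to their zero mean,
#' and `d`-fold differencing is inverted at the end.
#'
#' @param object An `arima_fit` or [arima_spec()].
#' @param horizon Number of steps ahead, >= 1.
#' @param history For the `arima_spec` method: a [daily_series] or numeric
#'   vector of past observations (given before `horizon`).
#' @param ... Unused.
#' @return A [forecast_result()] with method `"arima"`.
#' @export
forecast_arima <- function(object, ...) UseMethod("forecast_arima")

#' @rdname forecast_arima
#' @export
forecast_arima.arima_fit <- function(object, horizon, ...) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stopf("horizon must be >= 1")
  pr <- stats::predict(object$model, n.ahead = horizon)
  forecast_result("arima", fitted = object$fitted,
                  forecasts = as.numeric(pr$pred),
                  params = c(unclass(object$spec),
                             list(method = object$diagnostics$method,
                                  ljung_box_p = object$ljung_box$p.value)))
}

#' @rdname forecast_arima
#' @export
forecast_arima.arima_spec <- function(object, history, horizon, ...) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stopf("horizon must be >= 1")
  y <- series_values(history)
  s <- object
  w <- if (s$d > 0L) diff(y, differences = s$d) else y
  n <- length(w)
  if (n < s$p) stopf("history too short for an AR(%d) recursion", s$p)
  wc <- w - s$mean
  eps <- numeric(n)
  for (t in seq_len(n)) {
    if (t <= max(s$p, s$q)) next  # pre-sample innovations fixed at zero
    ar <- if (s$p) sum(s$phi * wc[t - seq_len(s$p)]) else 0
    ma <- if (s$q) sum(s$theta * eps[t - seq_len(s$q)]) else 0
    eps[t] <- wc[t] - ar + ma
  }
  wext <- c(wc, numeric(horizon))
  eext <- c(eps, numeric(horizon))  # future innovations at their mean
  for (m in seq_len(horizon)) {
    t <- n + m
    ar <- if (s$p) sum(s$phi * wext[t - seq_len(s$p)]) else 0
    ma <- if (s$q) sum(s$theta * eext[t - seq_len(s$q)]) else 0
    wext[t] <- ar - ma
  }
  fw <- wext[n + seq_len(horizon)] + s$mean
  fc <- if (s$d > 0L) {
    path <- stats::diffinv(c(w, fw), differences = s$d, xi = y[seq_len(s$d)])
    utils::tail(path, horizon)
  } else {
    fw
  }
  forecast_result("arima", fitted = rep(NA_real_, length(y)), forecasts = fc,
                  params = unclass(s))
}
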