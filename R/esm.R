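# Brown quadratic (triple) exponential smoothing.
#
# Three coupled smoothed statistics
#   S1_t = alpha x_t + (1 - alpha) S1_{t-1}
#   S2_t = alpha S1_t + (1 - alpha) S2_{t-1}
#   S3_t = alpha S2_t + (1 - alpha) S3_{t-1}
# yield at each t the local quadratic coefficients
#   a_t = 3 S1 - 3 S2 + S3
#   b_t = alpha [ (6 - 5a) S1 - (10 - 8a) S2 + (4 - 3a) S3 ] / (2 (1-a)^2)
#   c_t = alpha^2 (S1 - 2 S2 + S3) / (1-a)^2
# and the m-step forecast  Y_{t+m} = a_t + b_t m + 0.5 c_t m^2.

esm_coefficients <- function(alpha, s1, s2, s3) {
  om <- 1 - alpha
  list(
    a = 3 * s1 - 3 * s2 + s3,
    b = alpha * ((6 - 5 * alpha) * s1 - (10 - 8 * alpha) * s2 +
                   (4 - 3 * alpha) * s3) / (2 * om^2),
    c = alpha^2 * (s1 - 2 * s2 + s3) / om^2
  )
}

#' Fit Brown quadratic exponential smoothing
#'
#' Runs the three coupled smoothing recursions over the whole series and
#' tracks the quadratic coefficients `a_t`, `b_t`, `c_t` at every step. The
#' smoothing weight `alpha` of the latest observation defaults to the
#' customary experience value 0.15. All three statistics are initialised at
#' the mean of the first `n_init` observations (default 3). The one-step
#' fitted value at time `t` is the forecast made from the state at `t - 1`,
#' i.e. `a + b + c/2`; the first position has no history and is `NA`.
#'
#' Because the method tracks a local quadratic, it is asymptotically exact
#' on polynomial trends up to degree 2: on a long linear series `b_t`
#' approaches the slope and `c_t` approaches 0.
#'
#' @param series A [daily_series] or numeric vector, length >= 3.
#' @param alpha Smoothing weight in (0, 1); default 0.15.
#' @param n_init Number of leading observations averaged for the initial
#'   state (default 3).
#' @return An object of class `esm_fit`: final `state` (list with `alpha`,
#'   `s1`, `s2`, `s3`, `a`, `b`, `c`), per-step `trajectory` (data frame),
#'   `fitted`, and the training values.
#' @export
fit_esm <- function(series, alpha = 0.15, n_init = 3) {
  x <- series_values(series)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stopf("alpha must lie strictly between 0 and 1")
  }
  n_init <- as.integer(n_init)
  if (n_init < 1L) stopf("n_init must be >= 1")
  n <- length(x)
  if (n < max(3L, n_init)) stopf("need at least %d observations", max(3L, n_init))

  init <- mean(x[seq_len(n_init)])
  s1 <- s2 <- s3 <- a <- b <- cc <- numeric(n)
  p1 <- p2 <- p3 <- init
  for (t in seq_len(n)) {
    p1 <- alpha * x[t] + (1 - alpha) * p1
    p2 <- alpha * p1 + (1 - alpha) * p2
    p3 <- alpha * p2 + (1 - alpha) * p3
    s1[t] <- p1; s2[t] <- p2; s3[t] <- p3
    co <- esm_coefficients(alpha, p1, p2, p3)
    a[t] <- co$a; b[t] <- co$b; cc[t] <- co$c
  }
  fitted <- c(NA_real_, a[-n] + b[-n] + 0.5 * cc[-n])
  structure(
    list(state = list(alpha = alpha, s1 = p1, s2 = p2, s3 = p3,
                      a = a[n], b = b[n], c = cc[n]),
         trajectory = data.frame(s1 = s1, s2 = s2, s3 = s3,
                                 a = a, b = b, c = cc),
         fitted = fitted, values = x, init = init, n_init = n_init),
    class = "esm_fit"
  )
}

#' @export
print.esm_fit <- function(x, ...) {
  s <- x$state
  cat(sprintf("<esm_fit: alpha = %.3g, %d observations>\n", s$alpha,
              length(x$values)))
  cat(sprintf("  final state: a = %.5g, b = %.5g, c = %.5g\n", s$a, s$b, s$c))
  invisible(x)
}

#' Forecast from a smoothing state
#'
#' Extrapolates the local quadratic from the final state:
#' \eqn{Y_{t+m} = a_t + b_t m + 0.5\, c_t m^2} for `m = 1..horizon`.
#'
#' @param state An `esm_fit` from [fit_esm()], or a bare list with
#'   components `a`, `b`, `c` (and optionally `alpha`).
#' @param horizon Number of steps ahead, >= 1.
#' @return A [forecast_result()] with method `"esm"`.
#' @export
forecast_esm <- function(state, horizon) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stopf("horizon must be >= 1")
  fitted <- rep(NA_real_, 0L)
  if (inherits(state, "esm_fit")) {
    fitted <- state$fitted
    st <- state$state
  } else {
    st <- state
    stopifnot(all(c("a", "b", "c") %in% names(st)))
  }
  m <- seq_len(horizon)
  forecast_result("esm", fitted = fitted,
                  forecasts = st$a + st$b * m + 0.5 * st$c * m^2,
                  params = list(alpha = st$alpha, a = st$a, b = st$b, c = st$c))
}
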