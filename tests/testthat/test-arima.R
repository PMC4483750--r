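test_that("order selection finds autoregressive structure and honors fixed orders", {
  x <- simulate_arma(2000, phi = 0.7, seed = 201) + 60
  ord <- select_order(x, max_p = 3, max_q = 3)
  expect_gte(ord$p, 1L)
  expect_equal(ord$d, 0L)

  fixed <- select_order(x, fixed = c(2, 0, 3))
  expect_equal(c(fixed$p, fixed$d, fixed$q), c(2L, 0L, 3L))
  expect_identical(fixed$ic, "fixed")

  # deterministic for fixed input
  expect_identical(select_order(x, max_p = 2, max_q = 2),
                   select_order(x, max_p = 2, max_q = 2))
})

test_that("likelihood estimation recovers AR and MA coefficients", {
  x <- simulate_arma(2000, phi = 0.7, seed = 202)
  fit <- fit_arima(x, c(1, 0, 0))
  expect_lt(abs(fit$spec$phi - 0.7), 0.05)
  expect_identical(fit$diagnostics$method, "CSS-ML")

  # subtraction convention: theta simulated as +0.5 is estimated near +0.5
  y <- simulate_arma(2000, theta = 0.5, seed = 203)
  fit2 <- fit_arima(y, c(0, 0, 1))
  expect_lt(abs(fit2$spec$theta - 0.5), 0.06)
})

test_that("estimated coefficients fall within 3 standard errors across replicates", {
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    x <- simulate_arma(2000, phi = 0.6, seed = 7000 + r)
    fit <- suppressWarnings(fit_arima(x, c(1, 0, 0)))
    se <- sqrt(diag(fit$model$var.coef))[["ar1"]]
    if (abs(fit$spec$phi - 0.6) < 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("degenerate constant input is flagged, not silently fitted", {
  s <- mk_series(rep(50, 60))
  w <- capture_warnings(fit <- try(fit_arima(s, c(1, 0, 0)), silent = TRUE))
  expect_true(any(grepl("degenerate", w)))
  if (!inherits(fit, "try-error")) expect_lt(fit$spec$sigma2, 1e-8)
})

test_that("residual whiteness failure raises a warning", {
  # an AR(2) series deliberately underfitted with a mean-only model
  x <- simulate_arma(1000, phi = c(0.6, 0.3), seed = 204) + 50
  expect_warning(fit_arima(x, c(0, 0, 0)), "Ljung-Box")
})

test_that("closed-form forecasts from explicit specs are exact", {
  # mean-only model: every forecast equals the mean
  fc <- forecast_arima(arima_spec(0, 0, 0, mean = 56.75), c(50, 60, 55), 4)
  expect_equal(fc$forecasts, rep(56.75, 4))

  # AR(1) geometric decay toward the zero mean
  fc2 <- forecast_arima(arima_spec(1, 0, 0, phi = 0.5), c(1, 2, 8), 3)
  expect_equal(fc2$forecasts, c(4, 2, 1))

  # horizon contract
  fc3 <- forecast_arima(arima_spec(1, 0, 0, phi = 0.3, mean = 10),
                        c(9, 11, 10.5), 10)
  expect_length(fc3$forecasts, 10L)
  expect_true(all(is.finite(fc3$forecasts)))
  expect_error(forecast_arima(arima_spec(0, 0, 0), c(1, 2), 0), "horizon")
})

test_that("spec-based recursion agrees with the Kalman-filter predictor", {
  # dual route: conditional recursion vs stats::predict on the same model
  x <- simulate_arma(1500, phi = c(0.5, 0.2), theta = 0.4, seed = 205) + 30
  fit <- suppressWarnings(fit_arima(x, c(2, 0, 1)))
  a <- forecast_arima(fit, 8)$forecasts
  b <- forecast_arima(fit$spec, x, 8)$forecasts
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("differenced models forecast on the original scale", {
  # deterministic linear trend: an I(1) model with drift-free AR should
  # keep forecasts near the last level rather than revert to a global mean
  x <- simulate_arma(800, phi = 0.4, d = 1, seed = 206) + 500
  fit <- suppressWarnings(fit_arima(x, c(1, 1, 0)))
  fc <- forecast_arima(fit, 5)$forecasts
  expect_length(fc, 5L)
  expect_lt(abs(fc[1] - x[length(x)]), 20 * sd(diff(x)))
  b <- forecast_arima(fit$spec, x, 5)$forecasts
  expect_equal(fc, b, tolerance = 1e-2)
})

test_that("arima_spec validates its invariants", {
  expect_error(arima_spec(1, 3, 0, phi = 0.5), "d = 3")
  expect_error(arima_spec(2, 0, 0, phi = 0.5), "length")
  expect_error(arima_spec(0, 0, 2, theta = 0.5), "length")
})
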