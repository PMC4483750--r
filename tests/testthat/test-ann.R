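linear_recursion <- function(n = 200, phi = 0.9, b = 2, x1 = 5) {
  x <- numeric(n)
  x[1] <- x1
  for (t in 2:n) x[t] <- phi * x[t - 1] + b
  x
}

test_that("a noiseless linear recursion is learned to the target precision", {
  f <- fit_ann(linear_recursion(), ann_config(seed = 301))
  expect_true(f$training$reached_target)
  expect_lte(f$training$mse, 0.001)
  expect_lte(f$training$epochs, 20000L)
})

test_that("training is deterministic for identical series, config and seed", {
  x <- linear_recursion(150, 0.8, 5)
  f1 <- fit_ann(x, ann_config(seed = 302))
  f2 <- fit_ann(x, ann_config(seed = 302))
  expect_identical(f1$par, f2$par)
  expect_identical(forecast_ann(f1, 7)$forecasts, forecast_ann(f2, 7)$forecasts)
  f3 <- fit_ann(x, ann_config(seed = 303))
  expect_false(identical(f3$par, f1$par))
})

test_that("a constant series is reproduced within 1 percent", {
  f <- fit_ann(rep(50, 60), ann_config(seed = 304))
  fc <- forecast_ann(f, 5)
  expect_true(all(abs(fc$forecasts - 50) / 50 < 0.01))
})

test_that("zero hidden-to-output weights give the denormalized output bias", {
  L <- 3L; H <- 4L
  beta <- 0.25
  net <- structure(
    list(par = c(rep(0.3, L * H), rep(-0.1, H), rep(0, H), beta),
         lag_window = L, hidden_units = H,
         norm = list(lo = 20, hi = 60),
         config = ann_config(lag_window = L, hidden_units = H),
         values = c(30, 40, 50), fitted = rep(NA_real_, 3),
         training = list(epochs = 0L, mse = 0, reached_target = TRUE)),
    class = "ann_fit")
  fc <- forecast_ann(net, 4)
  denorm_beta <- (beta + 1) / 2 * (60 - 20) + 20
  expect_equal(fc$forecasts, rep(denorm_beta, 4))
})

test_that("iterated forecasts of a contraction converge to its fixed point", {
  # oscillating contraction x -> -0.5 x + 30: fixed point 20 lies in the
  # interior of the training range, so the learned map is accurate there
  f <- fit_ann(linear_recursion(250, -0.5, 30), ann_config(seed = 305))
  fc <- forecast_ann(f, 100)
  tail_val <- fc$forecasts[100]
  # independent fixed-point solve of the trained one-step map
  nm_lo <- f$norm$lo; nm_hi <- f$norm$hi
  step <- function(v) {
    z <- 2 * (v - nm_lo) / (nm_hi - nm_lo) - 1
    w <- f$par
    L <- f$lag_window; H <- f$hidden_units
    W1 <- matrix(w[seq_len(L * H)], L, H)
    b1 <- w[L * H + seq_len(H)]
    w2 <- w[L * H + H + seq_len(H)]
    b2 <- w[L * H + 2 * H + 1L]
    zo <- sum(tanh(rep(z, L) %*% W1 + b1) * w2) + b2
    (zo + 1) / 2 * (nm_hi - nm_lo) + nm_lo
  }
  fp <- uniroot(function(v) step(v) - v, c(nm_lo, nm_hi),
                extendInt = "yes", tol = 1e-10)$root
  expect_lt(abs(tail_val - fp), 1e-6 * max(1, abs(fp)))
  # the recursion's own fixed point (30 / (1 + 0.5) = 20) is nearby
  expect_lt(abs(tail_val - 20) / 20, 0.05)
})

test_that("configuration and length preconditions are enforced", {
  expect_error(ann_config(lag_window = 0), "lag_window")
  expect_error(ann_config(target_mse = 0), "target_mse")
  expect_error(fit_ann(c(1, 2, 3), ann_config(lag_window = 5)), "too short")
  f <- fit_ann(linear_recursion(60), ann_config(seed = 306))
  expect_error(forecast_ann(f, 0), "horizon")
  expect_length(forecast_ann(f, 10)$forecasts, 10L)
})

test_that("fitted values are NA-padded over the lag window", {
  f <- fit_ann(linear_recursion(60), ann_config(lag_window = 4, seed = 307))
  expect_true(all(is.na(f$fitted[1:4])))
  expect_true(all(!is.na(f$fitted[-(1:4)])))
  expect_length(f$fitted, 60L)
})
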