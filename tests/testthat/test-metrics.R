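test_that("the six indexes reproduce the published Guangzhou evaluation", {
  fx <- guangzhou()
  cfm <- evaluate_metrics(fx$actual, fx$cfm)
  expect_equal(round(cfm$mae, 4), 10.3321)
  expect_equal(round(cfm$mpe, 4), 0.2229)
  expect_equal(round(cfm$rmse, 4), 12.8903)
  expect_equal(round(cfm$theil_u, 4), 0.0025)
  expect_equal(round(cfm$bias_ratio, 4), 0.1739)
  expect_equal(round(cfm$variance_ratio, 4), 0.1757)

  arima <- evaluate_metrics(fx$actual, fx$arima)
  expect_equal(round(arima$mae, 4), 19.1119)
  expect_equal(round(arima$rmse, 4), 22.2286)

  anns <- evaluate_metrics(fx$actual, fx$anns)
  expect_equal(round(c(anns$mae, anns$mpe, anns$rmse, anns$theil_u,
                       anns$bias_ratio, anns$variance_ratio), 4),
               c(11.2298, 0.2571, 14.2652, 0.0032, 0.1203, 0.8789))
  esm <- evaluate_metrics(fx$actual, fx$esm)
  expect_equal(round(c(esm$mae, esm$mpe, esm$rmse, esm$theil_u,
                       esm$bias_ratio, esm$variance_ratio), 4),
               c(21.5435, 0.3987, 25.5865, 0.0034, 0.7089, 0.0616))
})

test_that("the Theil variant uses relative errors, not raw errors", {
  # the classical variant with raw errors in the numerator gives ~0.107 on
  # the Guangzhou combined column, ~40x the relative-error variant
  fx <- guangzhou()
  y <- fx$actual; yh <- fx$cfm
  classical <- sqrt(mean((y - yh)^2)) / (sqrt(mean(yh^2)) + sqrt(mean(y^2)))
  expect_equal(classical, 0.10658384596678987, tolerance = 1e-10)
  expect_equal(round(evaluate_metrics(y, yh)$theil_u, 4), 0.0025)
})

test_that("a perfect prediction scores zero on all six indexes", {
  y <- c(58.2, 64.4, 73.6)
  m <- evaluate_metrics(y, y)
  expect_equal(unlist(m[c("mae", "mpe", "rmse", "theil_u",
                          "bias_ratio", "variance_ratio")]),
               c(mae = 0, mpe = 0, rmse = 0, theil_u = 0,
                 bias_ratio = 0, variance_ratio = 0))
})

test_that("a 2-point pair matches direct formula evaluation", {
  m <- evaluate_metrics(c(10, 20), c(12, 18))
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, 2)
  expect_equal(m$mpe, 0.15)
  expect_equal(m$theil_u, 0.005082667219402194, tolerance = 1e-12)
  expect_equal(m$bias_ratio, 0)
  expect_equal(m$variance_ratio, 1)  # population sds 5 and 3, mse 4
})

test_that("MAE never exceeds RMSE and both are translation invariant", {
  set.seed(601)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    y <- abs(rnorm(n, 60, 20)) + 1
    yh <- y + rnorm(n, 0, 10)
    m <- evaluate_metrics(y, yh)
    expect_lte(m$mae, m$rmse + 1e-12)
    shift <- 100
    ms <- evaluate_metrics(y + shift, yh + shift)
    expect_equal(ms$mae, m$mae)
    expect_equal(ms$rmse, m$rmse)
    # the relative indexes are deliberately not invariant
    if (m$mpe > 0) expect_false(isTRUE(all.equal(ms$mpe, m$mpe)))
  }
})

test_that("input contracts are enforced", {
  expect_error(evaluate_metrics(c(1, 2), c(1, 2, 3)), "length mismatch")
  expect_error(evaluate_metrics(c(1, -2), c(1, 2)), "positive")
  expect_error(evaluate_metrics(c(5), c(5)), "at least 2")
  expect_error(evaluate_metrics(c(1, 2), c(1, NA)), "finite")
})
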