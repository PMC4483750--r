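test_that("min-max normalization maps rows onto [0, 1] by orientation", {
  X <- rbind(c(1, 3, 5), c(1, 3, 5))
  rb <- normalize_performance(X, "benefit")
  expect_equal(rb[1, ], c(0, 0.5, 1))
  rc <- normalize_performance(X, "cost")
  expect_equal(rc[1, ], c(1, 0.5, 0))

  Xd <- rbind(c(4, 4, 4), c(1, 2, 3))
  rd <- normalize_performance(Xd)
  expect_equal(rd[1, ], c(1, 1, 1))
  expect_equal(attr(rd, "degenerate_rows"), 1L)

  expect_error(normalize_performance(matrix(1:2, 2, 1)), "2 evaluation")
  expect_error(normalize_performance(rbind(c(1, NA), c(1, 2))), "finite")
})

test_that("the normalized entropy behaves at its extremes and on a known case", {
  expect_equal(entropy_index(c(1, 1, 1)), 1)
  expect_equal(entropy_index(c(1, 0)), 0)  # 0 * ln 0 taken as 0
  # direct evaluation of -(1/ln 3)(0.25 ln 0.25 + 0.25 ln 0.25 + 0.5 ln 0.5)
  expect_equal(entropy_index(c(1, 1, 2)), 0.94639463035718596, tolerance = 1e-13)
  expect_error(entropy_index(c(0, 0, 0)), "all-zero")
})

test_that("entropy is invariant to positive rescaling of the profile", {
  set.seed(501)
  for (i in 1:20) {
    r <- runif(sample(3:12, 1))
    k <- runif(1, 0.1, 100)
    expect_equal(entropy_index(k * r), entropy_index(r), tolerance = 1e-12)
  }
})

test_that("entropy weights are convex, symmetric and handle degeneracy", {
  expect_equal(entropy_weights(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(entropy_weights(c(0.9, 0.8)), c(1 / 3, 2 / 3))
  expect_warning(w <- entropy_weights(c(1, 1, 1)), "equal weights")
  expect_equal(w, rep(1 / 3, 3))

  set.seed(502)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1))
    lam <- suppressWarnings(entropy_weights(p))
    expect_true(all(lam >= 0))
    expect_equal(sum(lam), 1, tolerance = 1e-12)
  }
})

test_that("combination is a per-step convex weighted sum", {
  # convexity: identical method forecasts pass through unchanged
  f <- rbind(rep(3.7, 5), rep(3.7, 5), rep(3.7, 5))
  expect_equal(combine_forecasts(f, c(0.2, 0.5, 0.3)), rep(3.7, 5))

  # linearity and permutation equivariance
  A <- rbind(c(1, 2), c(3, 4))
  w <- c(0.25, 0.75)
  expect_equal(combine_forecasts(2 * A, w), 2 * combine_forecasts(A, w))
  expect_equal(combine_forecasts(A[2:1, ], w[2:1]), combine_forecasts(A, w))

  expect_error(combine_forecasts(A, c(0.5, 0.5, 0)), "weights")
  expect_error(combine_forecasts(A, c(-0.1, 1.1)), "non-negative")
  expect_error(combine_forecasts(A, c(0.5, 0.4)), "sum to 1")
})

test_that("the full weight chain matches an independent end-to-end computation", {
  # 3 methods x 4 time points; expected values computed independently by a
  # step-by-step evaluation of the normalize -> proportions -> entropy ->
  # weight chain on this exact matrix
  y <- c(50, 60, 40, 55)
  Yhat <- rbind(m1 = c(48, 66, 42, 50),
                m2 = c(55, 58, 30, 56),
                m3 = c(50.5, 61, 45, 49))
  w <- weights_from_history(y, Yhat, basis = "accuracy_benefit")
  expect_equal(unname(w$entropies),
               c(0.65364250431686277, 0.78051486902695832, 0.64280905337777683),
               tolerance = 1e-12)
  expect_equal(unname(w$weights),
               c(0.37523824236745307, 0.23778672556132627, 0.38697503207122086),
               tolerance = 1e-12)
  expect_named(w$weights, c("m1", "m2", "m3"))
})

test_that("identical methods share weight equally and rows permute with weights", {
  y <- c(10, 20, 30, 25)
  yh <- c(11, 18, 33, 24)
  w <- weights_from_history(y, rbind(a = yh, b = yh))
  expect_equal(unname(w$weights), c(0.5, 0.5))

  Yhat <- rbind(a = c(11, 18, 33, 24), b = c(9, 22, 28, 27),
                c = c(12, 19, 29, 23))
  w1 <- weights_from_history(y, Yhat)
  w2 <- weights_from_history(y, Yhat[c(3, 1, 2), ])
  expect_equal(unname(w2$weights), unname(w1$weights[c(3, 1, 2)]))
})

test_that("both performance bases produce valid convex weights", {
  set.seed(503)
  y <- abs(rnorm(30, 60, 15)) + 1
  Yhat <- rbind(y + rnorm(30, 0, 3), y + rnorm(30, 2, 8), rep(mean(y), 30))
  for (basis in c("accuracy_benefit", "abs_error_cost")) {
    w <- weights_from_history(y, Yhat, basis = basis)
    expect_true(all(w$weights >= 0))
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    expect_identical(w$basis, basis)
  }
})
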