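#' Neural-network configuration
#'
#' Settings for the lagged feed-forward network: one hidden layer of
#' hyperbolic-tangent units and a single linear output unit, trained on
#' (lag window -> next value) pairs after affine normalization of the data
#' to \[-1, 1\]. The defaults follow common practice for short univariate
#' concentration series: 5 lags, 5 hidden units, a training budget of
#' 20,000 iterations and a target mean squared error of 0.001 on the
#' normalized scale.
#'
#' @param lag_window Number of lagged values fed to the network (>= 1).
#' @param hidden_units Hidden-layer size (>= 1).
#' @param max_epochs Total optimisation-iteration budget.
#' @param target_mse Early-stopping target for the training MSE on the
#'   normalized \[-1, 1\] scale (> 0).
#' @param seed Seed for the weight initialisation; fixing it makes training
#'   fully reproducible.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(lag_window = 5, hidden_units = 5, max_epochs = 20000,
                       target_mse = 0.001, seed = 1) {
  lag_window <- as.integer(lag_window)
  hidden_units <- as.integer(hidden_units)
  max_epochs <- as.integer(max_epochs)
  if (lag_window < 1L) stopf("lag_window must be >= 1")
  if (hidden_units < 1L) stopf("hidden_units must be >= 1")
  if (max_epochs < 1L) stopf("max_epochs must be >= 1")
  if (!is.numeric(target_mse) || target_mse <= 0) stopf("target_mse must be > 0")
  structure(list(lag_window = lag_window, hidden_units = hidden_units,
                 max_epochs = max_epochs, target_mse = target_mse,
                 seed = seed),
            class = "ann_config")
}

# affine map of raw values onto [-1, 1]; a constant series maps to 0
ann_norm <- function(rng) {
  if (diff(rng) == 0) rng <- rng + c(-1, 1)
  list(lo = rng[1L], hi = rng[2L],
       fwd = function(x) 2 * (x - rng[1L]) / (rng[2L] - rng[1L]) - 1,
       inv = function(z) (z + 1) / 2 * (rng[2L] - rng[1L]) + rng[1L])
}

ann_unpack <- function(par, L, H) {
  list(W1 = matrix(par[seq_len(L * H)], L, H),
       b1 = par[L * H + seq_len(H)],
       w2 = par[L * H + H + seq_len(H)],
       b2 = par[L * H + 2 * H + 1L])
}

ann_predict_norm <- function(par, X, L, H) {
  w <- ann_unpack(par, L, H)
  A <- tanh(sweep(X %*% w$W1, 2, w$b1, `+`))
  drop(A %*% w$w2) + w$b2
}

#' Fit the lagged feed-forward network
#'
#' Builds (lag window -> next value) training pairs from the series,
#' normalizes inputs and target to \[-1, 1\], and trains a network with one
#' tanh hidden layer and a linear output by quasi-Newton (BFGS)
#' minimisation of the training MSE with an analytic gradient. Training
#' runs in bounded chunks and stops as soon as the normalized MSE reaches
#' `target_mse`, when the optimiser converges, or when the `max_epochs`
#' iteration budget is exhausted. Weights are initialised uniformly on
#' \[-0.5, 0.5\] under `config$seed`, so identical (series, config) inputs
#' give identical trained networks.
#'
#' @param series A [daily_series] or numeric vector, length
#'   `> lag_window + 1`.
#' @param config An [ann_config()].
#' @return An object of class `ann_fit`: the weight vector and layout, the
#'   normalization record, `fitted` (denormalized one-step predictions,
#'   `NA` for the first `lag_window` positions), the training trace
#'   (`epochs`, `mse`, `reached_target`), and the training values.
#' @export
fit_ann <- function(series, config = ann_config()) {
  stopifnot(inherits(config, "ann_config"))
  x <- series_values(series)
  L <- config$lag_window
  H <- config$hidden_units
  if (length(x) <= L + 1L) {
    stopf("series length %d too short for lag_window %d", length(x), L)
  }
  nm <- ann_norm(range(x))
  z <- nm$fwd(x)
  n_pairs <- length(z) - L
  X <- t(vapply(seq_len(n_pairs), function(i) z[i + seq_len(L) - 1L],
                numeric(L)))
  y <- z[L + seq_len(n_pairs)]

  obj <- function(par) {
    e <- ann_predict_norm(par, X, L, H) - y
    mean(e^2)
  }
  grad <- function(par) {
    w <- ann_unpack(par, L, H)
    Z1 <- sweep(X %*% w$W1, 2, w$b1, `+`)
    A <- tanh(Z1)
    e <- drop(A %*% w$w2) + w$b2 - y
    m <- length(e)
    gb2 <- 2 * mean(e)
    gw2 <- 2 / m * drop(crossprod(A, e))
    D <- (2 / m) * (e %o% w$w2) * (1 - A^2)  # back through tanh
    gW1 <- crossprod(X, D)
    gb1 <- colSums(D)
    c(as.vector(gW1), gb1, gw2, gb2)
  }

  n_par <- L * H + 2L * H + 1L
  par <- with_seed(config$seed, stats::runif(n_par, -0.5, 0.5))
  epochs <- 0L
  mse <- obj(par)
  reached <- mse <= config$target_mse
  while (!reached && epochs < config$max_epochs) {
    chunk <- min(500L, config$max_epochs - epochs)
    opt <- stats::optim(par, obj, grad, method = "BFGS",
                        control = list(maxit = chunk))
    par <- opt$par
    mse <- opt$value
    epochs <- epochs + chunk
    reached <- mse <= config$target_mse
    if (opt$convergence == 0L) break  # optimiser converged; no further progress
  }

  fitted_norm <- ann_predict_norm(par, X, L, H)
  structure(
    list(par = par, lag_window = L, hidden_units = H,
         norm = list(lo = nm$lo, hi = nm$hi),
         config = config, values = x,
         fitted = c(rep(NA_real_, L), nm$inv(fitted_norm)),
         training = list(epochs = epochs, mse = mse, reached_target = reached)),
    class = "ann_fit"
  )
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf("<ann_fit: %d lags -> %d tanh units -> linear>\n",
              x$lag_window, x$hidden_units))
  cat(sprintf("  training MSE %.3g after %d iterations (target %.3g %s)\n",
              x$training$mse, x$training$epochs, x$config$target_mse,
              if (x$training$reached_target) "reached" else "not reached"))
  invisible(x)
}

#' Forecast with a trained network
#'
#' Iterated one-step (recursive) forecasting: the network predicts one step
#' ahead from the last `lag_window` observations, the prediction is
#' appended to the window, and the process repeats for `horizon` steps.
#' Because the trained map is applied to its own output, long-horizon
#' forecasts of a contractive map converge to the map's fixed point.
#'
#' @param network An `ann_fit` from [fit_ann()].
#' @param horizon Number of steps ahead, >= 1.
#' @param history Optional [daily_series] or numeric vector to seed the lag
#'   window; defaults to the training series.
#' @return A [forecast_result()] with method `"ann"`.
#' @export
forecast_ann <- function(network, horizon, history = NULL) {
  stopifnot(inherits(network, "ann_fit"))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stopf("horizon must be >= 1")
  x <- if (is.null(history)) network$values else series_values(history)
  L <- network$lag_window
  if (length(x) < L) stopf("history shorter than the lag window (%d)", L)
  nm <- ann_norm(c(network$norm$lo, network$norm$hi))
  win <- nm$fwd(utils::tail(x, L))
  out <- numeric(horizon)
  for (m in seq_len(horizon)) {
    z <- ann_predict_norm(network$par, matrix(win, 1L), L, network$hidden_units)
    out[m] <- z
    win <- c(win[-1L], z)
  }
  forecast_result("ann", fitted = network$fitted, forecasts = nm$inv(out),
                  params = list(lag_window = L,
                                hidden_units = network$hidden_units,
                                epochs = network$training$epochs,
                                train_mse = network$training$mse,
                                seed = network$config$seed))
}
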