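#' Packaged Guangzhou PM2.5 evaluation set
#'
#' A published 10-day evaluation set for Guangzhou, China (22-31 January
#' 2015): actual 24-h mean PM2.5 concentrations alongside the forecasts of
#' an ARIMA model, a feed-forward neural network, Brown quadratic
#' exponential smoothing, and their entropy-weighted combination, all in
#' µg/m³. The combination weights used in that evaluation,
#' `(0.2399, 0.5419, 0.2182)` for (ARIMA, ANN, ESM), are returned
#' alongside; they were derived from a 416-day training record that is not
#' publicly printed, so here they serve as fixed inputs, never as a
#' fitting target.
#'
#' @return A list with `forecasts` (data frame: `date`, `actual`, `arima`,
#'   `anns`, `esm`, `cfm`) and `weights` (named numeric vector).
#' @examples
#' guangzhou_pm25()$weights
#' @export
guangzhou_pm25 <- function() {
  path <- system.file("extdata", "guangzhou_pm25_next10.csv",
                      package = "entrocast", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  list(forecasts = df,
       weights = c(arima = 0.2399, anns = 0.5419, esm = 0.2182))
}

#' Replay the Guangzhou evaluation arithmetic
#'
#' Recomputes, from the packaged fixture alone, (a) the combined forecast
#' column as the weighted sum of the three method columns under the fixed
#' published weights and (b) the six-index error report of every forecast
#' column against the actual observations. No model is fitted and no
#' random number is drawn: this separates "reproduce the published
#' arithmetic" (exact) from "reproduce the published fits" (impossible
#' without the unpublished training series).
#'
#' @param weights Combination weights applied to the (arima, anns, esm)
#'   columns; default the published triple from [guangzhou_pm25()].
#' @return A list with `table` (the fixture data frame plus a
#'   `cfm_recomputed` column), `weights`, and `metrics` (a named list of
#'   [evaluate_metrics()] reports for `arima`, `anns`, `esm`, `cfm`).
#' @export
replay_guangzhou <- function(weights = NULL) {
  fx <- guangzhou_pm25()
  if (is.null(weights)) weights <- fx$weights
  df <- fx$forecasts
  base <- t(as.matrix(df[, c("arima", "anns", "esm")]))
  df$cfm_recomputed <- combine_forecasts(base, weights)
  metrics <- lapply(c(arima = "arima", anns = "anns", esm = "esm", cfm = "cfm"),
                    function(col) evaluate_metrics(df$actual, df[[col]]))
  list(table = df, weights = weights, metrics = metrics)
}

#' Run the full combination-forecasting pipeline
#'
#' End-to-end workflow on one daily series: (1) hold out the final
#' `holdout` observations; (2) fit the requested base methods on the
#' training window; (3) derive entropy weights from the methods' in-sample
#' one-step prediction histories ([weights_from_history()]), restricted to
#' the positions where every method has a prediction; (4) forecast
#' `holdout + horizon` steps ahead with each method and combine them under
#' the fixed weights; (5) evaluate every forecast column against the
#' holdout observations with [evaluate_metrics()].
#'
#' The weights are computed once on the training window and held fixed
#' over the whole forecast horizon. With a single method the combination
#' degenerates to weight 1 and the combined column equals that method's
#' forecasts.
#'
#' @param series A [daily_series] (e.g. from [read_series()] or
#'   [simulate_pm25()]).
#' @param holdout Number of trailing observations held out for evaluation
#'   (default 10).
#' @param horizon Extra steps forecast beyond the holdout window
#'   (default 0).
#' @param methods Subset of `c("arima", "ann", "esm")` (default all).
#' @param basis Performance-matrix basis for [weights_from_history()].
#' @param order ARIMA order: `NULL` for automatic selection via
#'   [select_order()], or a length-3 vector to pin it.
#' @param alpha Smoothing weight for [fit_esm()] (default 0.15).
#' @param ann ANN settings, an [ann_config()]; its seed is replaced by
#'   `seed` unless the config is supplied explicitly.
#' @param seed Seed governing every random element of the run.
#' @param max_p,max_q Order-selection grid bounds (defaults 3, 3; see the
#'   package vignette for the choice).
#' @param output_dir Optional directory; when given, the forecast table
#'   (CSV), weights and metrics (JSON) and a run log are written there,
#'   stamped with the seed and a hash of the configuration.
#' @return An object of class `cfm_run`: list with `forecasts` (data
#'   frame: date, actual where known, one column per method, `cfm`),
#'   `weights` (the [weights_from_history()] record or `NULL` for a single
#'   method), `metrics`, `fits`, and `config`.
#' @export
run_pipeline <- function(series, holdout = 10, horizon = 0,
                         methods = c("arima", "ann", "esm"),
                         basis = c("accuracy_benefit", "abs_error_cost"),
                         order = NULL, alpha = 0.15, ann = NULL, seed = 1,
                         max_p = 3, max_q = 3, output_dir = NULL) {
  stopifnot(inherits(series, "daily_series"))
  basis <- match.arg(basis)
  methods <- match.arg(methods, c("arima", "ann", "esm"), several.ok = TRUE)
  holdout <- as.integer(holdout)
  horizon <- as.integer(horizon)
  if (horizon < 0L) stopf("pipeline stage 'config': horizon must be >= 0")
  if (is.null(ann)) ann <- ann_config(seed = seed)
  h <- holdout + horizon

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s': %s", name, conditionMessage(e))
    })
  }

  sp <- stage("split", split_holdout(series, holdout))
  train <- sp$train
  log_lines <- c(sprintf("n_train = %d, holdout = %d, horizon = %d, seed = %s",
                         nrow(train), holdout, horizon, format(seed)))

  fits <- list()
  fcasts <- list()
  if ("arima" %in% methods) {
    stage("arima", {
      ord <- if (is.null(order)) {
        select_order(train, max_p = max_p, max_q = max_q)
      } else {
        select_order(train, fixed = order)
      }
      fit <- suppressWarnings(fit_arima(train, ord))
      fits$arima <- fit
      fcasts$arima <- forecast_arima(fit, h)
      log_lines <- c(log_lines,
                      sprintf("arima: order (%d,%d,%d) by %s, Ljung-Box p = %.3g",
                              ord$p, ord$d, ord$q, ord$ic,
                              fit$ljung_box$p.value))
    })
  }
  if ("ann" %in% methods) {
    stage("ann", {
      fit <- fit_ann(train, ann)
      fits$ann <- fit
      fcasts$ann <- forecast_ann(fit, h)
      log_lines <- c(log_lines,
                      sprintf("ann: %d lags, %d hidden; MSE %.3g after %d iterations (target %s)",
                              ann$lag_window, ann$hidden_units,
                              fit$training$mse, fit$training$epochs,
                              if (fit$training$reached_target) "reached" else "not reached"))
    })
  }
  if ("esm" %in% methods) {
    stage("esm", {
      fit <- fit_esm(train, alpha = alpha)
      fits$esm <- fit
      fcasts$esm <- forecast_esm(fit, h)
      log_lines <- c(log_lines,
                      sprintf("esm: alpha = %.3g, init (mean of first %d) = %.4g",
                              alpha, fit$n_init, fit$init))
    })
  }

  weights_fit <- NULL
  if (length(methods) == 1L) {
    lambda <- stats::setNames(1, methods)
  } else {
    stage("weights", {
      fitted_mat <- do.call(rbind, lapply(fcasts, function(f) f$fitted))
      ok <- colSums(is.na(fitted_mat)) == 0L
      if (sum(ok) < 2L) stopf("fewer than 2 common in-sample positions")
      weights_fit <- weights_from_history(train$value[ok], fitted_mat[, ok],
                                           basis = basis)
    })
    lambda <- weights_fit$weights
    log_lines <- c(log_lines,
                   sprintf("weights (%s): %s", basis,
                           paste(sprintf("%s = %.4f", names(lambda), lambda),
                                 collapse = ", ")))
  }

  fmat <- do.call(rbind, lapply(fcasts, function(f) f$forecasts))
  cfm <- combine_forecasts(fmat, lambda)

  dates <- series$date[nrow(series)] - holdout + seq_len(h)
  out <- data.frame(date = dates,
                    actual = c(sp$test$value, rep(NA_real_, horizon)))
  for (m in names(fcasts)) out[[m]] <- fcasts[[m]]$forecasts
  out$cfm <- cfm

  metrics <- stage("evaluate", {
    lapply(out[, c(names(fcasts), "cfm"), drop = FALSE], function(col) {
      evaluate_metrics(sp$test$value, col[seq_len(holdout)])
    })
  })

  config <- list(holdout = holdout, horizon = horizon, methods = methods,
                 basis = basis, order = order, alpha = alpha,
                 ann = unclass(ann), seed = seed,
                 max_p = max_p, max_q = max_q)
  run <- structure(
    list(forecasts = out, weights = weights_fit,
         weight_vector = lambda, metrics = metrics, fits = fits,
         config = config, log = log_lines),
    class = "cfm_run"
  )
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.cfm_run <- function(x, ...) {
  cat("<cfm_run>\n")
  for (line in x$log) cat(" ", line, "\n")
  cat("  holdout metrics (MAE):",
      paste(sprintf("%s = %.4f", names(x$metrics),
                    vapply(x$metrics, `[[`, numeric(1), "mae")),
            collapse = ", "), "\n")
  invisible(x)
}

# Write run artifacts: forecast CSV, weights + metrics JSON, log. Every file
# set is stamped with the seed and an md5 of the serialized configuration.
write_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(run$config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  stamp <- list(seed = run$config$seed,
                config_md5 = unname(tools::md5sum(cfg_path)))
  utils::write.csv(run$forecasts, file.path(output_dir, "forecasts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(stamp, list(basis = run$config$basis,
                  weights = as.list(run$weight_vector),
                  entropies = if (!is.null(run$weights)) run$weights$entropies)),
    file.path(output_dir, "weights.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  jsonlite::write_json(
    c(stamp, lapply(run$metrics, unclass)),
    file.path(output_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("config_md5: %s", stamp$config_md5), run$log),
             file.path(output_dir, "run.log"))
  invisible(output_dir)
}
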