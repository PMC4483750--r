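#' Min-max normalization of a performance matrix
#'
#' Normalizes each method's performance profile (one row per method, one
#' column per evaluation time point) to \[0, 1\] by the row's range. For a
#' benefit orientation (higher is better) `r = (x - min) / (max - min)`;
#' for a cost orientation (lower is better) `r = (max - x) / (max - min)`.
#' A constant row carries no ranking information; it is mapped to all ones
#' (the maximal-entropy profile, whose combination weight is then driven to
#' zero) and flagged in the `"degenerate_rows"` attribute.
#'
#' @param X Numeric matrix, `m >= 2` methods by `n >= 2` time points, all
#'   entries finite.
#' @param orientation `"benefit"` (default) or `"cost"`.
#' @return A matrix `r` of the same shape with entries in \[0, 1\] and
#'   attribute `degenerate_rows` (integer indices of constant rows).
#' @export
normalize_performance <- function(X, orientation = c("benefit", "cost")) {
  orientation <- match.arg(orientation)
  X <- as.matrix(X)
  if (ncol(X) < 2L) stopf("need at least 2 evaluation time points (columns)")
  if (nrow(X) < 2L) stopf("need at least 2 methods (rows)")
  if (any(!is.finite(X))) stopf("performance matrix entries must be finite")
  degenerate <- integer(0)
  r <- X
  for (i in seq_len(nrow(X))) {
    lo <- min(X[i, ]); hi <- max(X[i, ])
    if (hi == lo) {
      r[i, ] <- 1
      degenerate <- c(degenerate, i)
    } else if (orientation == "benefit") {
      r[i, ] <- (X[i, ] - lo) / (hi - lo)
    } else {
      r[i, ] <- (hi - X[i, ]) / (hi - lo)
    }
  }
  attr(r, "degenerate_rows") <- degenerate
  r
}

#' Normalized Shannon entropy of a performance profile
#'
#' Converts a non-negative profile `r` into proportions
#' `f_j = r_j / sum(r)` and returns the Shannon entropy scaled by
#' `1 / ln(n)` so that the result lies in \[0, 1\]: 1 for a uniform
#' profile, 0 for a point mass. Zero proportions contribute nothing
#' (`0 ln 0 = 0` by convention). The entropy is invariant to positive
#' rescaling of the profile.
#'
#' @param r Non-negative numeric vector (one method's normalized profile)
#'   or a matrix of such rows.
#' @param n Number of time points used in the `1 / ln(n)` scaling; defaults
#'   to the profile length.
#' @return The normalized entropy in \[0, 1\] (a vector, one per row, for
#'   matrix input).
#' @export
entropy_index <- function(r, n = NULL) {
  if (is.matrix(r)) {
    return(vapply(seq_len(nrow(r)), function(i) entropy_index(r[i, ], n),
                  numeric(1)))
  }
  r <- as.numeric(r)
  if (any(r < 0)) stopf("profile entries must be non-negative")
  if (sum(r) == 0) stopf("all-zero profile: proportions are undefined")
  if (is.null(n)) n <- length(r)
  if (n < 2) stopf("entropy scaling needs n >= 2")
  f <- r / sum(r)
  f <- f[f > 0]
  p <- -sum(f * log(f)) / log(n)
  min(max(p, 0), 1)
}

#' Entropy weights
#'
#' Turns per-method entropies into combination weights
#' \deqn{\lambda_i = \frac{1 - p_i}{m - \sum_i p_i}.}
#' A method whose accuracy profile is nearly uniform over time (entropy
#' close to 1) carries little discriminating information and receives a
#' small weight; a dispersed profile (low entropy) receives a large one.
#' The weights are non-negative and sum to 1 on every path: when every
#' entropy equals 1 the denominator vanishes and the function falls back
#' to equal weights with a warning.
#'
#' @param p Numeric vector of entropies in \[0, 1\], length `m >= 2`.
#' @return Numeric weight vector of length `m`, non-negative, summing to 1.
#' @export
entropy_weights <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 2L) stopf("need entropies for at least 2 methods")
  if (any(p < -1e-12 | p > 1 + 1e-12)) stopf("entropies must lie in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  denom <- length(p) - sum(p)
  if (denom <= 1e-12) {
    warnf("all methods have maximal entropy; falling back to equal weights")
    return(rep(1 / length(p), length(p)))
  }
  lambda <- (1 - p) / denom
  lambda / sum(lambda)
}

#' Combine forecasts with convex weights
#'
#' Per-step weighted sum of the base methods' forecasts,
#' \eqn{\hat x = k_1 \hat x_1 + \dots + k_m \hat x_m} with
#' \eqn{k_i \ge 0,\ \sum k_i = 1}. Because the weights are convex, each
#' combined value lies between the smallest and largest method forecast at
#' that step.
#'
#' @param forecasts Numeric matrix, `m` methods (rows) by `h` steps
#'   (columns); a vector is taken as a single step.
#' @param weights Numeric vector of length `m`; non-negative, summing to 1
#'   within `1e-9`.
#' @return Numeric vector of `h` combined forecasts.
#' @examples
#' combine_forecasts(rbind(101.6861, 61.6869, 114.865),
#'                   c(0.2399, 0.5419, 0.2182))
#' @export
combine_forecasts <- function(forecasts, weights) {
  if (!is.matrix(forecasts)) forecasts <- matrix(forecasts, ncol = 1L)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(forecasts)) {
    stopf("%d weights for %d method rows", length(weights), nrow(forecasts))
  }
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stopf("weights must sum to 1 (got %.12g)", sum(weights))
  }
  drop(crossprod(forecasts, weights))[seq_len(ncol(forecasts))]
}

#' Entropy weights from historical predictive performance
#'
#' The full chain from in-sample predictions to combination weights. A
#' performance matrix is built from each method's prediction history
#' against the actuals, normalized per method ([normalize_performance()]),
#' converted to entropies ([entropy_index()]) and then to weights
#' ([entropy_weights()]).
#'
#' Two standard constructions of the performance matrix are offered:
#' \describe{
#'   \item{`accuracy_benefit` (default)}{per-point forecasting accuracy
#'     `1 - |y - yhat| / y`, floored at 0, treated as a benefit object;}
#'   \item{`abs_error_cost`}{per-point absolute relative error
#'     `|y - yhat| / y`, treated as a cost object.}
#' }
#' Both weight methods by the dispersion of their accuracy profile over
#' time; the basis actually used is recorded in the result.
#'
#' @param y Actual values, strictly positive, length `n >= 2`.
#' @param Yhat Numeric matrix of in-sample predictions, `m >= 2` methods by
#'   `n` time points (rows may be named by method).
#' @param basis `"accuracy_benefit"` or `"abs_error_cost"`.
#' @return An object of class `entropy_weights_fit`: list with the raw
#'   performance `matrix`, normalized `r`, proportions `f`, `entropies`,
#'   `weights` (named like `Yhat`'s rows), `basis`, `orientation`, and
#'   `degenerate_rows`.
#' @export
weights_from_history <- function(y, Yhat,
                                 basis = c("accuracy_benefit", "abs_error_cost")) {
  basis <- match.arg(basis)
  y <- series_values(y)
  Yhat <- as.matrix(Yhat)
  if (ncol(Yhat) != length(y)) {
    stopf("Yhat has %d columns but y has %d points", ncol(Yhat), length(y))
  }
  if (length(y) < 2L) stopf("need at least 2 evaluation points")
  if (any(y <= 0)) stopf("actual values must be strictly positive")
  rel_err <- abs(sweep(Yhat, 2L, y)) / rep(y, each = nrow(Yhat))
  if (basis == "accuracy_benefit") {
    X <- pmax(1 - rel_err, 0)
    orientation <- "benefit"
  } else {
    X <- rel_err
    orientation <- "cost"
  }
  r <- normalize_performance(X, orientation)
  f <- r / rowSums(r)
  p <- entropy_index(r)
  lambda <- entropy_weights(p)
  names(lambda) <- rownames(Yhat)
  structure(
    list(matrix = X, r = r, f = f, entropies = p, weights = lambda,
         basis = basis, orientation = orientation,
         degenerate_rows = attr(r, "degenerate_rows")),
    class = "entropy_weights_fit"
  )
}

#' @export
print.entropy_weights_fit <- function(x, ...) {
  cat(sprintf("<entropy_weights_fit: %d methods, %d points, basis '%s'>\n",
              nrow(x$matrix), ncol(x$matrix), x$basis))
  w <- signif(x$weights, 5)
  nm <- if (is.null(names(w))) seq_along(w) else names(w)
  cat("  weights:", paste(sprintf("%s = %s", nm, w), collapse = ", "), "\n")
  cat("  entropies:", paste(signif(x$entropies, 5), collapse = ", "), "\n")
  invisible(x)
}
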