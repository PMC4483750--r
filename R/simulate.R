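#' Simulate a PM2.5-like daily concentration series
#'
#' Seeded generator of a positive daily series with the qualitative
#' structure of urban PM2.5 records in subtropical China: annual
#' seasonality peaking in winter (mid-January by default) and bottoming in
#' summer, plus short-range autocorrelated noise. The model is
#' \deqn{x_t = \max(\mathrm{floor},\ \mu + A \cos(2\pi (d_t - d_0)/365.25) + e_t)}
#' with day-of-year \eqn{d_t}, peak day \eqn{d_0}, and AR(1) noise
#' \eqn{e_t = \phi e_{t-1} + \epsilon_t} whose Gaussian innovations are
#' scaled so that `e` has stationary standard deviation `noise_sd`. The
#' positive floor keeps the series compatible with the [daily_series]
#' positivity invariant. The defaults (annual mean 55 µg/m³, amplitude
#' 25 µg/m³, lag-1 autocorrelation 0.6, noise sd 12 µg/m³) give winters
#' around 80 µg/m³ and summers around 30 µg/m³, a realistic span for a
#' polluted coastal city.
#'
#' @param n_days Number of consecutive days (>= 1).
#' @param annual_mean Mean level, µg/m³ (default 55).
#' @param seasonal_amplitude Half peak-to-trough seasonal swing, µg/m³
#'   (default 25); 0 removes seasonality.
#' @param peak_day Day-of-year of the seasonal maximum (default 15,
#'   mid-January).
#' @param ar_coefficient Lag-1 autocorrelation of the noise, `|.| < 1`
#'   (default 0.6).
#' @param noise_sd Stationary standard deviation of the noise, µg/m³
#'   (default 12); 0 gives a deterministic series.
#' @param floor Minimum value, µg/m³ (default 1, must be > 0).
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @param start_date First calendar date (default `"2013-12-02"`).
#' @return A [daily_series] of `n_days` consecutive days.
#' @examples
#' simulate_pm25(30, seed = 7)
#' @export
simulate_pm25 <- function(n_days, annual_mean = 55, seasonal_amplitude = 25,
                          peak_day = 15, ar_coefficient = 0.6, noise_sd = 12,
                          floor = 1, seed = 1,
                          start_date = as.Date("2013-12-02")) {
  n_days <- as.integer(n_days)
  if (n_days < 1L) stopf("n_days must be >= 1")
  if (seasonal_amplitude < 0) stopf("seasonal_amplitude must be >= 0")
  if (abs(ar_coefficient) >= 1) stopf("|ar_coefficient| must be < 1")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (floor <= 0) stopf("floor must be > 0")

  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  seasonal <- annual_mean +
    seasonal_amplitude * cos(2 * pi * (doy - peak_day) / 365.25)
  e <- if (noise_sd == 0) {
    numeric(n_days)
  } else {
    innov_sd <- noise_sd * sqrt(1 - ar_coefficient^2)
    with_seed(seed, {
      if (ar_coefficient == 0) {
        stats::rnorm(n_days, sd = innov_sd)
      } else {
        as.numeric(stats::arima.sim(model = list(ar = ar_coefficient),
                                    n = n_days, sd = innov_sd, n.start = 200))
      }
    })
  }
  daily_series(dates, pmax(floor, seasonal + e))
}

#' Simulate an ARMA / ARIMA process
#'
#' Seeded Gaussian ARMA generator for parameter-recovery and
#' order-selection testing, built on [stats::arima.sim()] with a discarded
#' burn-in. Coefficients use the same subtraction convention as
#' [arima_spec()] (\eqn{\theta_q(B) = 1 - \theta_1 B - \dots}), so a series
#' simulated with `theta = 0.5` should be estimated by [fit_arima()] with
#' `theta` near 0.5. If the supplied AR polynomial is non-stationary a
#' warning is issued (the recursion is still run). The result is
#' cumulatively summed `d` times at the end.
#'
#' @param n Number of observations after burn-in (>= 1).
#' @param phi AR coefficients (may be empty).
#' @param theta MA coefficients, subtraction convention (may be empty).
#' @param d Integration order (default 0).
#' @param innovation_sd Innovation standard deviation (default 1).
#' @param seed RNG seed.
#' @param burn_in Burn-in length, >= 200 (default 200).
#' @return Numeric vector of length `n`.
#' @export
simulate_arma <- function(n, phi = numeric(0), theta = numeric(0), d = 0,
                          innovation_sd = 1, seed = 1, burn_in = 200) {
  n <- as.integer(n)
  if (n < 1L) stopf("n must be >= 1")
  d <- as.integer(d)
  burn_in <- max(200L, as.integer(burn_in))
  ar_stationary <- polyroot_ok(phi)
  if (!ar_stationary) {
    warnf("AR polynomial is not stationary; simulated series may diverge")
  }
  x <- with_seed(seed, {
    if (!length(phi) && !length(theta)) {
      stats::rnorm(n, sd = innovation_sd)
    } else if (ar_stationary) {
      model <- list()
      if (length(phi)) model$ar <- phi
      if (length(theta)) model$ma <- -theta  # convert to arima.sim's convention
      as.numeric(stats::arima.sim(model = model, n = n, sd = innovation_sd,
                                  n.start = burn_in + length(phi) + length(theta)))
    } else {
      # explosive AR: run the recursion directly from zero initial conditions
      p <- length(phi); q <- length(theta)
      ns <- burn_in + n
      eps <- stats::rnorm(ns + q, sd = innovation_sd)
      z <- numeric(ns)
      for (t in seq_len(ns)) {
        ma <- eps[t + q] - if (q) sum(theta * eps[t + q - seq_len(q)]) else 0
        lags <- t - seq_len(p)
        ar <- if (p) sum(phi[lags > 0] * z[lags[lags > 0]]) else 0
        z[t] <- ar + ma
      }
      utils::tail(z, n)
    }
  })
  if (d > 0L) {
    for (k in seq_len(d)) x <- cumsum(x)
  }
  x
}
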