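# Growth-rate fitting, the acclimation rule, oxygen-evolution rates and the
# small normalisations used throughout the physiological results.

#' Exponential growth rate from a monitored time series
#'
#' Specific growth rate mu (d^-1) as the OLS slope of `ln(signal)` against
#' day, over either a caller-supplied window or an automatically selected
#' exponential-phase window: the contiguous window of at least
#' `min_window` points with the highest R^2 of the log-linear fit, ties
#' broken towards longer, then earlier, windows.
#'
#' @param day Sampling days, increasing; at least 3 points spanning >= 1 day.
#' @param signal In-vivo Chla fluorescence or cell density, > 0.
#' @param window Optional integer index range (e.g. `2:6`) to fit over.
#' @param min_window Minimum window length for automatic selection.
#' @return List of class `growth_fit`: `mu` (d^-1), `window`, `r_squared`,
#'   `intercept`.
#' @export
#' @examples
#' d <- 0:4
#' fit_growth_rate(d, 100 * exp(0.51 * d))$mu # 0.51
fit_growth_rate <- function(day, signal, window = NULL, min_window = 4L) {
  n <- length(day)
  if (n < 3L || length(signal) != n)
    stop("need >= 3 paired (day, signal) observations")
  if (diff(range(day)) < 1) stop("series must span at least one day")
  if (any(diff(day) <= 0)) stop("days must be increasing")
  if (is.null(window)) {
    window <- best_loglinear_window(day, signal, min_window = min(min_window, n))
  } else {
    window <- as.integer(window)
    if (min(window) < 1L || max(window) > n)
      stop("window out of range")
  }
  s <- signal[window]
  if (any(!is.finite(s)) || any(s <= 0))
    stop("signal must be positive over the fitting window")
  fit <- stats::lm(log(s) ~ day[window])
  structure(
    list(mu = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         window = window,
         r_squared = loglinear_r2(day[window], s)),
    class = "growth_fit")
}

# R^2 of the log-linear fit, robust to perfect fits (no summary.lm noise).
loglinear_r2 <- function(day, signal) {
  y <- log(signal)
  res <- stats::lm.fit(cbind(1, day), y)$residuals
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(if (sum(res^2) == 0) 1 else 0)
  max(0, 1 - sum(res^2) / sst)
}

# Deterministic exponential-phase selection: best R^2 among contiguous
# windows, preferring longer then earlier windows on (near-)ties.
best_loglinear_window <- function(day, signal, min_window = 4L) {
  n <- length(day)
  min_window <- max(3L, min(min_window, n))
  best <- NULL
  best_key <- c(-Inf, -Inf, Inf)  # (rounded R2, length, -start)
  for (start in 1:(n - min_window + 1)) {
    for (end in (start + min_window - 1):n) {
      idx <- start:end
      s <- signal[idx]
      if (any(!is.finite(s)) || any(s <= 0)) next
      r2 <- loglinear_r2(day[idx], s)
      key <- c(round(r2, 10), length(idx), -start)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] &&
           key[3] > best_key[3])) {
        best <- idx
        best_key <- key
      }
    }
  }
  if (is.null(best)) stop("no usable window with positive signal")
  best
}

#' Acclimation check over successive transfers
#'
#' Cultures are considered acclimated when growth rates over five successive
#' transfers (roughly 40 cell divisions) vary by less than 15%. Variation is
#' `(max - min) / mean` by default; a coefficient-of-variation alternative
#' is selectable. The threshold is strict: variation exactly at it fails.
#'
#' @param rates Growth rates (d^-1) over >= 5 successive transfers.
#' @param threshold Relative-variation threshold (default 0.15).
#' @param statistic `"range"` for (max-min)/mean, `"cv"` for sd/mean.
#' @return `TRUE` if acclimated.
#' @export
#' @examples
#' acclimation_check(c(1, 1, 1, 1, 1.2)) # FALSE (~19% variation)
acclimation_check <- function(rates, threshold = 0.15,
                              statistic = c("range", "cv")) {
  statistic <- match.arg(statistic)
  if (length(rates) < 5L) stop("need growth rates from >= 5 transfers")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be finite and positive")
  variation <- switch(statistic,
                      range = (max(rates) - min(rates)) / mean(rates),
                      cv = stats::sd(rates) / mean(rates))
  variation < threshold
}

#' Growth rate relative to the maximum, in percent
#'
#' @param mu Observed growth rate, d^-1.
#' @param mu_max Maximum growth rate of the strain, d^-1, > 0. A small
#'   (5%) overshoot of `mu` above `mu_max` is tolerated for noisy rates.
#' @return `100 * mu / mu_max`.
#' @export
#' @examples
#' relative_growth(0.51, 1.05) # 48.6%
relative_growth <- function(mu, mu_max) {
  if (any(!is.finite(mu_max)) || any(mu_max <= 0))
    stop("mu_max must be positive")
  if (any(mu < 0) || any(mu > mu_max * 1.05))
    stop("mu must lie in [0, 1.05 * mu_max]")
  100 * mu / mu_max
}

#' Linear oxygen rate from an electrode trace
#'
#' OLS slope of dissolved O2 against time, scaled to hourly units. Positive
#' during illuminated phases (net evolution), negative in the dark
#' (respiration).
#'
#' @param time_s Time in seconds, >= 5 points, not all equal.
#' @param O2 Dissolved O2, umol L^-1.
#' @return Rate in umol O2 L^-1 h^-1 (signed).
#' @export
#' @examples
#' t <- 0:9 * 30
#' linear_rate(t, 200 + 0.01 * t) # 36
linear_rate <- function(time_s, O2) {
  if (length(time_s) < 5L || length(O2) != length(time_s))
    stop("need >= 5 paired (time, O2) observations")
  if (stats::sd(time_s) == 0) stop("time vector is constant")
  unname(stats::coef(stats::lm(O2 ~ time_s))[2]) * 3600
}

#' Signed percent change between two values
#'
#' @param before Reference value, non-zero.
#' @param after New value.
#' @return `100 * (after - before) / before`.
#' @export
#' @examples
#' percent_change(123, 36) # -70.7%
percent_change <- function(before, after) {
  if (any(before == 0)) stop("reference value must be non-zero")
  100 * (after - before) / before
}

#' Equivalent-sphere cell volume from Coulter diameter
#'
#' `(pi/6) d^3` with d in um, i.e. femtolitres (1 um^3 = 1 fL). Diatom cells
#' are not perfect spheres; the equivalent sphere is the convention used for
#' per-volume normalisations here.
#'
#' @param d Cell diameter, um, > 0.
#' @return Volume in fL.
#' @export
#' @examples
#' volume_from_diameter(5) # 65.45 fL
volume_from_diameter <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameter must be positive")
  pi / 6 * d^3
}

#' Read a growth time series from CSV (`day, signal`)
#' @param file CSV path.
#' @return data.frame with columns `day`, `signal`.
#' @export
read_growth_csv <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("day", "signal") %in% names(df)))
    stop("growth CSV must have columns day, signal")
  df
}

#' Read an oxygen-electrode trace from CSV (`time_s, O2_umol_L, phase`)
#' @param file CSV path.
#' @return data.frame with columns `time_s`, `O2_umol_L`, `phase`.
#' @export
read_o2_csv <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("time_s", "O2_umol_L", "phase") %in% names(df)))
    stop("O2 CSV must have columns time_s, O2_umol_L, phase")
  df
}
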