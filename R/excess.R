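#' Split a decomposition into non-trend and trend series
#'
#' The non-trend ("detail") series is the element-wise sum of the low-order
#' modes `c_1..c_m`; the trend series is the sum of the remaining modes plus
#' the residual. Their sum reproduces the input exactly up to floating error.
#' The detail series holds the short-term fluctuations — the excess/deficit
#' deaths — while the trend series is the mortality expected under normal
#' conditions.
#'
#' @param decomp an `emd` object.
#' @param partition a `trend_partition` from [classify_trend()], or an
#'   integer split index `m`.
#' @return List with numeric vectors `non_trend` and `trend`.
#' @export
partition_series <- function(decomp, partition) {
  stopifnot(inherits(decomp, "emd"))
  m <- if (inherits(partition, "trend_partition")) partition$m
       else as.integer(partition)
  N <- decomp$nimf
  if (m < 1 || m > N) stop("split index m = ", m, " outside 1..", N)
  non_trend <- rowSums(decomp$imfs[, seq_len(m), drop = FALSE])
  trend <- decomp$residual
  if (m < N)
    trend <- trend + rowSums(decomp$imfs[, (m + 1):N, drop = FALSE])
  list(non_trend = non_trend, trend = trend)
}

#' Excess deaths over an event window
#'
#' Sums the non-trend series over the inclusive event window. The window is
#' matched by calendar date when dates are supplied, by index otherwise.
#' Rounding is to the nearest integer, half away from zero.
#'
#' @param non_trend numeric detail series.
#' @param window inclusive window: Date (or "start:end" string) when `dates`
#'   is given, else an integer index range `c(from, to)`.
#' @param dates optional `Date` vector aligned with `non_trend`.
#' @return List with `total` (exact sum), `rounded` (integer), `daily`
#'   (data frame of the window's daily values) and the resolved `window`.
#' @export
excess_deaths <- function(non_trend, window, dates = NULL) {
  if (!is.null(dates)) {
    w <- parse_window(window)
    if (w[1] < dates[1] || w[2] > dates[length(dates)])
      stop("window ", w[1], "..", w[2], " outside the series range ",
           dates[1], "..", dates[length(dates)])
    idx <- which(dates >= w[1] & dates <= w[2])
  } else {
    w <- as.integer(window)
    if (length(w) != 2 || w[1] > w[2] || w[1] < 1 || w[2] > length(non_trend))
      stop("index window outside the series range")
    idx <- w[1]:w[2]
  }
  if (!length(idx)) stop("event window does not overlap the series")
  daily <- non_trend[idx]
  total <- sum(daily)
  list(total = total,
       rounded = round_half_away(total),
       daily = data.frame(date = if (!is.null(dates)) dates[idx] else idx,
                          excess = daily),
       window = w)
}

round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Daily log relative risk
#'
#' `log RR(t) = ln(X(t) / trend(t))`: the observed mortality against the
#' mortality expected under normal conditions (the trend series), on the
#' natural-log scale. The trend must be strictly positive everywhere. A
#' zero-count day yields `-Inf` with a warning; setting
#' `zero_correction = TRUE` applies the continuity correction
#' `ln((X + 0.5) / trend)` on those days instead.
#'
#' @param x observed series (numeric or [daily_series]).
#' @param trend expected ("normal-conditions") series, strictly positive.
#' @param zero_correction apply the +0.5 continuity correction on zero-count
#'   days (default FALSE).
#' @return Numeric log-RR series.
#' @export
log_relative_risk <- function(x, trend, zero_correction = FALSE) {
  v <- as_values(x)
  dates <- as_dates(x)
  if (length(v) != length(trend)) stop("series and trend lengths differ")
  bad <- which(trend <= 0)
  if (length(bad)) {
    at <- if (!is.null(dates)) format(dates[bad[1]]) else paste("index", bad[1])
    stop("trend is not strictly positive at ", at,
         ": relative risk undefined")
  }
  zero <- v == 0
  if (any(zero) && zero_correction) v[zero] <- v[zero] + 0.5
  out <- log(v / trend)
  if (any(zero) && !zero_correction)
    warning(sum(zero), " zero-count day(s) produced -Inf log RR; ",
            "set zero_correction = TRUE for the +0.5 correction")
  out
}

#' Ordinary least-squares excess-risk regression
#'
#' Fits `logRR ~ covariates` by OLS with an intercept over an optional event
#' window, reporting coefficient estimates, standard errors, two-sided
#' t-test p-values and the adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param data data frame containing a `logRR` column and the covariate
#'   columns (and a `date` column if `window` is used).
#' @param covariates character vector of covariate column names (at least 1).
#' @param window optional inclusive date window restricting the fit.
#' @return List of class `excess_lm`: `coefficients` (data frame with
#'   estimate, std_error, t, p_value), `adj_r_squared`, `n`, `covariates`,
#'   and the underlying `lm` fit as `model`.
#' @export
fit_excess_regression <- function(data, covariates, window = NULL) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  missing_cols <- setdiff(c("logRR", covariates), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.null(window)) {
    if (!"date" %in% names(data)) stop("window given but no date column")
    w <- parse_window(window)
    data <- data[data$date >= w[1] & data$date <= w[2], , drop = FALSE]
  }
  n <- nrow(data)
  if (n < length(covariates) + 3)
    stop("need at least ", length(covariates) + 3,
         " observations in the window, got ", n)
  if (any(!is.finite(data$logRR)))
    stop("non-finite logRR values in the regression window")
  f <- stats::as.formula(paste("logRR ~", paste(covariates, collapse = " + ")))
  fit <- stats::lm(f, data = data)
  if (fit$rank < length(covariates) + 1)
    stop("rank-deficient design: collinear covariates")
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t", "p_value")
  structure(list(coefficients = coefs,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 n = n, covariates = covariates, model = fit),
            class = "excess_lm")
}

#' @export
print.excess_lm <- function(x, ...) {
  cat("Excess-risk regression: logRR ~",
      paste(x$covariates, collapse = " + "),
      " (n =", x$n, ")\n")
  print(round(x$coefficients, 5))
  cat("Adjusted R-squared:", round(x$adj_r_squared, 4), "\n")
  invisible(x)
}

#' @export
coef.excess_lm <- function(object, ...) stats::coef(object$model)

#' Temperature anomaly via the same decomposition machinery
#'
#' Decomposes a daily maximum temperature series by EMD and sums the modes
#' whose time scales overlap the mortality non-trend band, giving the
#' temperature anomaly (departure from the seasonal/long-term norm). Scale
#' matching is by average period: a temperature mode belongs to the anomaly
#' while its average period does not exceed the geometric midpoint between
#' the periods of mortality modes `m` and `m+1` (the dyadic gap between the
#' non-trend and trend scales). When that cutoff is unavailable — no trend
#' modes, or degenerate periods — the fall-back is to reuse the mortality
#' split count `m` directly.
#'
#' @param temperature a [daily_series] (or numeric) of daily maximum
#'   temperature.
#' @param mortality_decomp the mortality `emd` object.
#' @param mortality_partition its `trend_partition`.
#' @param sift_iterations passed to [emd()].
#' @return List: `anomaly` (numeric series), `trend`, `m_temp` (modes used),
#'   `decomp` (the temperature decomposition).
#' @export
temperature_anomaly <- function(temperature, mortality_decomp,
                                mortality_partition, sift_iterations = 10L) {
  d_temp <- emd(temperature, sift_iterations = sift_iterations)
  m <- mortality_partition$m
  per_mort <- average_periods(mortality_decomp)
  per_temp <- average_periods(d_temp)
  cutoff <- NA_real_
  if (m < length(per_mort) && is.finite(per_mort[m]) &&
      is.finite(per_mort[m + 1]))
    cutoff <- sqrt(per_mort[m] * per_mort[m + 1])
  m_temp <- if (is.finite(cutoff)) {
    ok <- which(per_temp <= cutoff)
    if (length(ok)) max(ok) else min(m, d_temp$nimf)
  } else min(m, d_temp$nimf)
  parts <- partition_series(d_temp, m_temp)
  list(anomaly = parts$non_trend, trend = parts$trend, m_temp = m_temp,
       decomp = d_temp)
}

#' Classical seasonal decomposition comparator
#'
#' The standard moving-average decomposition (via [stats::decompose()]):
#' trend = centred moving average of window `frequency` (undefined for
#' `floor(frequency/2)` samples at each end — the end-effect that makes this
#' decomposition blind to events near the record boundaries), seasonal = the
#' average annual pattern of the detrended data recentred to mean zero and
#' tiled, random = the rest. Provided as the comparator the adaptive
#' decomposition is judged against.
#'
#' @param x numeric vector or [daily_series] (length at least 2 cycles).
#' @param frequency cycle length in days (default 365).
#' @return List with numeric vectors `trend`, `seasonal`, `random` (trend
#'   and random contain `NA` at the ends) and the `frequency` used.
#' @export
classical_decompose <- function(x, frequency = 365) {
  v <- as_values(x)
  if (length(v) < 2 * frequency)
    stop("need at least two full cycles (", 2 * frequency, " points), got ",
         length(v))
  dec <- stats::decompose(stats::ts(v, frequency = frequency))
  list(trend = as.numeric(dec$trend),
       seasonal = as.numeric(dec$seasonal),
       random = as.numeric(dec$random),
       frequency = frequency)
}

#' Heatwave excess mortality by Hilbert-Huang decomposition
#'
#' The headline pipeline: decompose a daily mortality series (EMD, or
#' batch-averaged ensemble EMD when the two disagree), separate trend from
#' non-trend modes by the energy significance test, and derive the
#' epidemiological outputs — excess deaths summed over the event window, the
#' daily excess series, the trend ("normal conditions") series and the daily
#' log relative risk.
#'
#' With `method = "auto"` both decompositions are run and their significance
#' tests compared: agreement means plain EMD suffices; disagreement is the
#' mode-mixing symptom and the ensemble partition is used.
#'
#' @param series daily mortality, a [daily_series] or data frame with
#'   `date`, `value`.
#' @param window inclusive event window (`c(start, end)` dates or
#'   `"start:end"`).
#' @param method `"emd"`, `"eemd"` (batch-averaged, post-processed) or
#'   `"auto"`.
#' @param level significance band, 95 (default) or 99.
#' @param mode noise model for the test: `"auto"`, `"white"`,
#'   `"generalized"`.
#' @param seed integer seed; required for the ensemble paths.
#' @param sift_iterations,ensemble_size,noise_factor,batches decomposition
#'   configuration.
#' @param n_fit_imfs generalized-test fit length.
#' @param zero_correction passed to [log_relative_risk()].
#' @return Object of class `hht_excess`: the decomposition, partition,
#'   `excess` (window totals and daily table), `trend`, `non_trend`,
#'   `logRR`, `method_used` and the call. `fitted()` returns the trend
#'   series, `residuals()` the detail series.
#' @examples
#' \donttest{
#' sim <- gen_mortality(mortality_scenario(seed = 7))
#' fit <- hht_excess(sim$mortality, window = c("2004-02-18", "2004-02-23"),
#'                   method = "emd")
#' fit$excess$total
#' }
#' @export
hht_excess <- function(series, window, method = c("emd", "eemd", "auto"),
                       level = 95, mode = "auto", seed = NULL,
                       sift_iterations = 10L, ensemble_size = 100L,
                       noise_factor = 0.1, batches = 20L, n_fit_imfs = 3L,
                       zero_correction = FALSE) {
  method <- match.arg(method)
  values <- as_values(series)
  dates <- as_dates(series)
  if (method != "emd" && is.null(seed))
    stop("the ensemble paths require `seed`")

  if (method == "auto") {
    agr <- emd_eemd_agreement(series, seed = seed, level = level, mode = mode,
                              n_fit_imfs = n_fit_imfs,
                              sift_iterations = sift_iterations,
                              ensemble_size = ensemble_size,
                              noise_factor = noise_factor, batches = batches)
    if (agr$agreement) {
      decomp <- agr$decomp_emd; partition <- agr$partition_emd
      method_used <- "emd"
    } else {
      decomp <- agr$decomp_eemd; partition <- agr$partition_eemd
      method_used <- "eemd"
    }
  } else if (method == "emd") {
    decomp <- emd(series, sift_iterations = sift_iterations)
    partition <- classify_trend(decomp, level = level, mode = mode,
                                n_fit_imfs = n_fit_imfs)
    method_used <- "emd"
    agr <- NULL
  } else {
    decomp <- batch_eemd(series, batches = batches,
                         ensemble_size = ensemble_size,
                         noise_factor = noise_factor, seed = seed,
                         sift_iterations = sift_iterations)
    partition <- classify_trend(decomp, level = level, mode = mode,
                                n_fit_imfs = n_fit_imfs)
    method_used <- "eemd"
    agr <- NULL
  }

  parts <- partition_series(decomp, partition)
  excess <- excess_deaths(parts$non_trend, window, dates = dates)
  logRR <- if (all(parts$trend > 0))
    log_relative_risk(values, parts$trend, zero_correction = zero_correction)
  else {
    warning("trend series not strictly positive; log RR not computed")
    NULL
  }
  structure(list(decomposition = decomp, partition = partition,
                 excess = excess, non_trend = parts$non_trend,
                 trend = parts$trend, logRR = logRR, dates = dates,
                 x = values, method_used = method_used, agreement = agr,
                 seed = seed, call = match.call()),
            class = "hht_excess")
}

#' @export
print.hht_excess <- function(x, ...) {
  w <- x$excess$window
  cat("Heatwave excess mortality (Hilbert-Huang decomposition)\n")
  cat("  method: ", x$method_used, "; non-trend modes: 1..", x$partition$m,
      " of ", x$decomposition$nimf, " (", x$partition$mode, " noise model, ",
      x$partition$level, "% band)\n", sep = "")
  cat("  window ", format(w[1]), " .. ", format(w[2]), " (",
      nrow(x$excess$daily), " days)\n", sep = "")
  cat("  excess deaths: ", format(x$excess$total, digits = 4),
      " (rounded: ", x$excess$rounded, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.hht_excess <- function(object, ...) {
  out <- list(excess = object$excess,
              m = object$partition$m,
              method = object$method_used,
              spectrum = spectrum_table(object$partition),
              average_periods = average_periods(object$decomposition))
  class(out) <- "summary.hht_excess"
  out
}

#' @export
print.summary.hht_excess <- function(x, ...) {
  cat("Excess deaths:", format(x$excess$total, digits = 4),
      "(rounded:", x$excess$rounded, ")\n")
  cat("Split index m =", x$m, "| method:", x$method, "\n\n")
  cat("Average periods (days):\n")
  print(round(x$average_periods, 1))
  cat("\nEnergy spectrum (log2):\n")
  print(round(x$spectrum, 3))
  invisible(x)
}

#' @export
fitted.hht_excess <- function(object, ...) object$trend

#' @export
residuals.hht_excess <- function(object, ...) object$non_trend

#' Plot the fitted excess-mortality decomposition
#'
#' Three panels: the series with its trend overlaid, the detail (non-trend)
#' series with the event window shaded, and the energy spectrum with its
#' confidence bands.
#'
#' @param x an `hht_excess` object.
#' @param ... passed on to the panel plots.
#' @export
plot.hht_excess <- function(x, ...) {
  t <- if (!is.null(x$dates)) x$dates else seq_along(x$x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(t, x$x, type = "l", col = "grey50", ylab = "deaths/day",
                 main = "series and trend", ...)
  graphics::lines(t, x$trend, lwd = 2)
  graphics::plot(t, x$non_trend, type = "l", ylab = "excess deaths/day",
                 main = "detail (non-trend) series", ...)
  w <- x$excess$window
  graphics::abline(v = w, lty = 2)
  plot.energy_spectrum(x$partition$spectrum,
                       main = "IMF energy significance test")
  invisible(x)
}
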