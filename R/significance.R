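#' Observed IMF energies
#'
#' Raw sum of squares of each mode over the full record, `E_k = sum_i
#' d_k(i)^2` — no per-sample normalisation. The significance test works in
#' log2-energy space, where a constant normalisation would cancel anyway, but
#' the raw-sum convention is kept throughout so spectra and confidence bands
#' stay directly comparable.
#'
#' @param decomp an `emd` object.
#' @return Numeric vector `E_1..E_N`.
#' @export
imf_energies <- function(decomp) {
  stopifnot(inherits(decomp, "emd"))
  if (decomp$nimf == 0) return(numeric(0))
  colSums(decomp$imfs^2)
}

#' White-noise energy model for higher-order modes
#'
#' For Gaussian white noise the expected mode energies follow the geometric
#' decay `W_Hk = (E_1 / 0.719) * 2.01^(-k)` for `k >= 2`, anchored at the
#' observed first-mode energy: log2 energy falls on a straight line of slope
#' `-log2(2.01) ~= -1.007` against the mode index. Modes whose observed
#' energy sits significantly above this line are trend, not noise.
#'
#' @param E1 observed energy of the first mode (must be positive).
#' @param N total number of modes.
#' @return Named numeric vector `W_H2..W_HN` (strictly decreasing).
#' @export
white_noise_energy_model <- function(E1, N) {
  if (E1 <= 0) stop("first-mode energy must be positive")
  if (N < 2) stop("need at least 2 modes")
  k <- 2:N
  w <- (E1 / 0.719) * 2.01^(-k)
  names(w) <- paste0("k", k)
  w
}

#' Confidence-band ordinates for the noise energy line
#'
#' Upper 95% and 99% band ordinates in log2-energy units:
#' `upper95[k] = log2(W_Hk) + 2^(0.474k - 2.449)` and
#' `upper99[k] = log2(W_Hk) + 2^(0.460k - 1.919)`. The margins widen with the
#' mode index, reflecting the shrinking effective degrees of freedom of
#' low-frequency modes; the 99% band lies above the 95% band for every index
#' of practical size (they cross only beyond k = 37).
#'
#' @param model output of [white_noise_energy_model()] (energies for
#'   `k = 2..N`), or any positive vector on that index range.
#' @return List with numeric vectors `upper95` and `upper99` (log2 units).
#' @export
confidence_bands <- function(model) {
  k <- 2:(length(model) + 1)
  base <- log2(model)
  list(upper95 = base + 2^(0.474 * k - 2.449),
       upper99 = base + 2^(0.460 * k - 1.919))
}

# margins alone (log2 units), reused when the band is shifted onto a fitted
# noise line in the generalized (serially-correlated) test
band_margins <- function(k, level) {
  if (level == 95) 2^(0.474 * k - 2.449) else 2^(0.460 * k - 1.919)
}

#' Separate trend from non-trend modes by the energy significance test
#'
#' Compares observed log2 mode energies with a noise energy line plus
#' confidence band and flags exceedances as trend modes. Three modes of
#' operation:
#' \describe{
#'   \item{white}{the line is the white-noise model anchored at the observed
#'     first-mode energy ([white_noise_energy_model()]).}
#'   \item{generalized}{for serially-correlated noise: an ordinary
#'     least-squares line through `(k, log2 E_k)` for the first `n_fit_imfs`
#'     modes replaces the anchored line, and the same band margins are laid
#'     on top of it.}
#'   \item{auto}{starts white; if the first three modes misfit the anchored
#'     line (RMS log2 deviation > 1), switches to generalized — the
#'     fractional-noise pathway.}
#' }
#' The first mode is never flagged (it anchors the model; the band starts at
#' k = 2). The non-trend block must be contiguous from mode 1: the split
#' index `m` is the last index below the first flagged mode, so an isolated
#' non-exceedance above a flagged mode is absorbed into the trend side. When
#' nothing is flagged, `m = N` and the trend side is the residual alone.
#'
#' @param decomp an `emd` object with at least 3 modes.
#' @param level operative confidence band, 95 (default) or 99; both bands are
#'   always computed and reported.
#' @param mode `"auto"`, `"white"` or `"generalized"`.
#' @param n_fit_imfs how many low-order modes define the generalized fit
#'   (default 3).
#' @return A list of class `trend_partition`: `m`, `non_trend_indices`,
#'   `trend_indices`, `mode` (the mode actually used), `level`, `flagged`,
#'   and `spectrum`, an `energy_spectrum` object carrying `energies`,
#'   `model`, `upper95`, `upper99` and (generalized mode) `fitted_line`.
#' @export
classify_trend <- function(decomp, level = 95, mode = c("auto", "white", "generalized"),
                           n_fit_imfs = 3L) {
  mode <- match.arg(mode)
  if (!level %in% c(95, 99)) stop("level must be 95 or 99")
  E <- imf_energies(decomp)
  N <- length(E)
  if (N < 3) stop("too few IMFs to run the significance test (need N >= 3)")
  if (any(E <= 0)) stop("zero-energy IMF: significance test undefined")
  k_all <- seq_len(N)
  logE <- log2(E)

  white_line <- log2(E[1] / 0.719) - k_all * log2(2.01)
  used_mode <- mode
  if (mode == "auto") {
    rms <- sqrt(mean((logE[1:3] - white_line[1:3])^2))
    used_mode <- if (rms > 1.0) "generalized" else "white"
  }

  k <- 2:N
  model <- white_noise_energy_model(E[1], N)
  bands <- confidence_bands(model)
  fitted_line <- NULL
  if (used_mode == "white") {
    line_k <- log2(model)                      # log2 W_Hk on k = 2..N
  } else {
    kf <- seq_len(min(n_fit_imfs, N))
    fit <- stats::lm.fit(cbind(1, kf), logE[kf])
    fitted_line <- c(intercept = unname(fit$coefficients[1]),
                     slope = unname(fit$coefficients[2]))
    line_k <- fitted_line["intercept"] + fitted_line["slope"] * k
  }
  up95 <- line_k + band_margins(k, 95)
  up99 <- line_k + band_margins(k, 99)
  upper <- if (level == 95) up95 else up99
  flagged <- k[logE[k] > upper]

  m <- if (length(flagged)) min(flagged) - 1L else N
  spectrum <- structure(list(energies = E, model = model,
                             upper95 = up95, upper99 = up99,
                             fitted_line = fitted_line, k_band = k),
                        class = "energy_spectrum")
  structure(list(m = m,
                 non_trend_indices = seq_len(m),
                 trend_indices = if (m < N) (m + 1L):N else integer(0),
                 mode = used_mode, level = level, flagged = flagged,
                 spectrum = spectrum),
            class = "trend_partition")
}

#' @export
print.trend_partition <- function(x, ...) {
  N <- length(x$spectrum$energies)
  cat("Trend/non-trend partition (", x$mode, " noise model, ", x$level,
      "% band)\n", sep = "")
  cat("  non-trend: IMFs 1..", x$m, "; trend: ",
      if (length(x$trend_indices))
        paste0("IMFs ", min(x$trend_indices), "..", N, " + residual")
      else "residual only", "\n", sep = "")
  invisible(x)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  print(spectrum_table(x))
  invisible(x)
}

#' Tabulate an energy spectrum for export or plotting
#'
#' @param spectrum an `energy_spectrum` (or a `trend_partition`, whose
#'   spectrum is used).
#' @return Data frame with mode index, log2 observed energy, log2 model
#'   energy and both band ordinates (model columns `NA` at k = 1).
#' @export
spectrum_table <- function(spectrum) {
  if (inherits(spectrum, "trend_partition")) spectrum <- spectrum$spectrum
  N <- length(spectrum$energies)
  data.frame(k = seq_len(N),
             log2_energy = log2(spectrum$energies),
             log2_model = c(NA, log2(spectrum$model)),
             upper95 = c(NA, spectrum$upper95),
             upper99 = c(NA, spectrum$upper99))
}

#' Plot an energy spectrum with its confidence bands
#'
#' The semi-log display of the significance test: observed log2 energies
#' (points/line), the noise energy line, and the 95%/99% upper bands.
#'
#' @param x an `energy_spectrum` object.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.energy_spectrum <- function(x, ...) {
  tab <- spectrum_table(x)
  ylim <- range(tab[, -1], na.rm = TRUE)
  graphics::plot(tab$k, tab$log2_energy, type = "b", pch = 8,
                 xlab = "IMF index k", ylab = "log2 energy", ylim = ylim, ...)
  graphics::lines(tab$k, tab$log2_model, type = "b", pch = 1)
  graphics::lines(tab$k, tab$upper95, lty = 3)
  graphics::lines(tab$k, tab$upper99, lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 1, 3, 2),
                   pch = c(8, 1, NA, NA),
                   legend = c("observed", "noise model", "95% band", "99% band"))
  invisible(x)
}

#' Do EMD- and EEMD-based significance tests agree?
#'
#' Runs the significance test on a plain EMD decomposition and on a
#' batch-averaged EEMD decomposition of the same series and compares the two
#' partitions. Agreement means plain EMD suffices; disagreement is the
#' operational symptom of mode mixing, and the EEMD partition should be used.
#'
#' Partitions are compared by scale, not by raw index: the ensemble's
#' post-processing frequently inserts an extra fine-scale component at the
#' front, shifting every order index by one while leaving the physical split
#' unchanged. The tests agree when the coarsest non-trend average period of
#' the two partitions differs by less than three quarters of an octave
#' (under the dyadic spacing of modes, identical splits differ by far less
#' and splits one mode apart by a full octave).
#'
#' @param x numeric vector or [daily_series].
#' @param seed integer seed for the EEMD side.
#' @param level,mode,n_fit_imfs passed to [classify_trend()].
#' @param sift_iterations,ensemble_size,noise_factor,batches decomposition
#'   configuration.
#' @return List of class `emd_eemd_agreement`: `agreement` (logical),
#'   `m_emd`, `m_eemd`, the coarsest non-trend periods `scale_emd` /
#'   `scale_eemd` (days), both `trend_partition` objects and both
#'   decompositions.
#' @export
emd_eemd_agreement <- function(x, seed, level = 95, mode = "auto",
                               n_fit_imfs = 3L, sift_iterations = 10L,
                               ensemble_size = 100L, noise_factor = 0.1,
                               batches = 20L) {
  d_emd <- emd(x, sift_iterations = sift_iterations)
  d_eemd <- batch_eemd(x, batches = batches, ensemble_size = ensemble_size,
                       noise_factor = noise_factor, seed = seed,
                       sift_iterations = sift_iterations)
  p_emd <- classify_trend(d_emd, level = level, mode = mode,
                          n_fit_imfs = n_fit_imfs)
  p_eemd <- classify_trend(d_eemd, level = level, mode = mode,
                           n_fit_imfs = n_fit_imfs)
  coarsest <- function(decomp, m) {
    per <- average_periods(decomp)[seq_len(m)]
    per <- per[!is.na(per)]
    if (length(per)) max(per) else NA_real_
  }
  s_emd <- coarsest(d_emd, p_emd$m)
  s_eemd <- coarsest(d_eemd, p_eemd$m)
  agree <- is.finite(s_emd) && is.finite(s_eemd) &&
    abs(log2(s_emd / s_eemd)) <= 0.75
  structure(list(agreement = agree,
                 m_emd = p_emd$m, m_eemd = p_eemd$m,
                 scale_emd = s_emd, scale_eemd = s_eemd,
                 partition_emd = p_emd, partition_eemd = p_eemd,
                 decomp_emd = d_emd, decomp_eemd = d_eemd),
            class = "emd_eemd_agreement")
}

#' @export
print.emd_eemd_agreement <- function(x, ...) {
  cat("EMD m =", x$m_emd, " (coarsest detail period ",
      format(x$scale_emd, digits = 3), " d) | EEMD m = ", x$m_eemd, " (",
      format(x$scale_eemd, digits = 3), " d) ->\n  ",
      if (x$agreement) "agree: plain EMD is sufficient"
      else "disagree: mode mixing suspected, use the EEMD partition",
      "\n", sep = "")
  invisible(x)
}

#' Sample autocorrelation with white-noise bands
#'
#' Thin wrapper around [stats::acf()] adding the usual `±1.96/sqrt(n)`
#' approximate 95% band, used to diagnose serial correlation in the non-trend
#' series (the trigger for the generalized significance test).
#'
#' @param x numeric vector or [daily_series].
#' @param max_lag largest lag (must satisfy `1 <= max_lag < n`).
#' @return Data frame with columns `lag` (0..max_lag) and `acf`; the band
#'   half-width is attached as attribute `band`.
#' @export
acf_bands <- function(x, max_lag) {
  v <- as_values(x)
  n <- length(v)
  if (max_lag < 1 || max_lag >= n) stop("need 1 <= max_lag < n")
  a <- stats::acf(v, lag.max = max_lag, plot = FALSE)
  out <- data.frame(lag = 0:max_lag, acf = as.numeric(a$acf))
  attr(out, "band") <- 1.96 / sqrt(n)
  out
}
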