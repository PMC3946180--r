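#' Instantaneous frequency and amplitude of one mode
#'
#' Hilbert spectral analysis of a single intrinsic mode function: the analytic
#' signal is formed in the frequency domain (FFT with positive frequencies
#' doubled and negative frequencies zeroed), its modulus is the instantaneous
#' amplitude, and the centred finite difference of the unwrapped phase divided
#' by `2*pi*dt` is the instantaneous frequency in cycles per day. The first
#' and last two samples are masked invalid — phase estimates there rest on
#' one-sided information. Negative instantaneous frequencies (physically
#' dubious samples, typically where the mode's amplitude is tiny) are retained
#' but flagged, not clipped.
#'
#' @param imf numeric vector, length at least 16.
#' @param dt sampling step in days (default 1).
#' @return A data frame with columns `frequency` (cycles/day), `amplitude`,
#'   `valid` (end-mask) and `negative_frequency`.
#' @examples
#' sp <- instantaneous_spectrum(sin(2 * pi * (0:799) / 20))
#' median(sp$frequency[sp$valid])   # ~ 0.05 cycles/day
#' @export
instantaneous_spectrum <- function(imf, dt = 1) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 16) stop("mode too short for Hilbert analysis (need length >= 16)")
  if (max(x) - min(x) < .Machine$double.eps * max(1, max(abs(x)))) {
    # constant mode: zero amplitude, frequency undefined everywhere
    return(data.frame(frequency = rep(NA_real_, n), amplitude = rep(0, n),
                      valid = rep(FALSE, n),
                      negative_frequency = rep(FALSE, n)))
  }
  z <- analytic_signal(x)
  amplitude <- Mod(z)
  phase <- unwrap_phase(Arg(z))
  freq <- rep(NA_real_, n)
  i <- 2:(n - 1)
  freq[i] <- (phase[i + 1] - phase[i - 1]) / (2 * 2 * pi * dt)
  freq[1] <- (phase[2] - phase[1]) / (2 * pi * dt)
  freq[n] <- (phase[n] - phase[n - 1]) / (2 * pi * dt)
  valid <- rep(TRUE, n)
  valid[c(1, 2, n - 1, n)] <- FALSE
  data.frame(frequency = freq, amplitude = amplitude, valid = valid,
             negative_frequency = !is.na(freq) & freq < 0)
}

# analytic signal via the FFT: zero out negative frequencies, double the
# positive ones, keep DC (and Nyquist for even n) untouched
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Average period of one mode
#'
#' Series length divided by the number of strict local maxima (the
#' [find_extrema()] convention), in days for daily data. On noise the average
#' periods of successive modes roughly double — the dyadic filter-bank
#' signature of the decomposition.
#'
#' @param imf numeric vector.
#' @param n the sample size to divide by; defaults to `length(imf)`.
#' @return Average period in days.
#' @export
average_period <- function(imf, n = length(imf)) {
  npeaks <- length(find_extrema(imf)$maxima)
  if (npeaks == 0)
    stop("mode has no local maxima: average period undefined")
  n / npeaks
}

#' Average periods of every mode in a decomposition
#'
#' @param decomp an `emd` object.
#' @return Named numeric vector, one period per IMF (NA where a mode has no
#'   maxima).
#' @export
average_periods <- function(decomp) {
  stopifnot(inherits(decomp, "emd"))
  n <- length(decomp$x)
  out <- vapply(seq_len(decomp$nimf), function(j) {
    npk <- length(find_extrema(decomp$imfs[, j])$maxima)
    if (npk == 0) NA_real_ else n / npk
  }, numeric(1))
  names(out) <- colnames(decomp$imfs)
  out
}

#' Write the per-mode instantaneous spectrum to CSV
#'
#' Columns `date,frequency,amplitude,valid` (plus the negative-frequency
#' flag), one row per sample.
#'
#' @param spectrum output of [instantaneous_spectrum()].
#' @param path output path.
#' @param dates optional `Date` vector; defaults to the sample index.
#' @export
write_spectrum_csv <- function(spectrum, path, dates = NULL) {
  out <- cbind(date = if (!is.null(dates)) format(dates)
                      else seq_len(nrow(spectrum)),
               spectrum)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
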