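#' Locate strict interior extrema
#'
#' Finds local maxima and minima of a sequence. A flat plateau bounded by
#' strictly lower (resp. higher) neighbours counts as a single extremum,
#' placed at the plateau's first index; endpoints are never extrema. This
#' deterministic tie-break makes sifting and average-period estimates
#' reproducible on integer-valued count data, where ties are common.
#'
#' @param values numeric vector, length at least 3.
#' @return A list with integer vectors `maxima` and `minima` (1-based indices).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0))   # maxima 2, minima 4
#' @export
find_extrema <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 points to locate interior extrema")
  r <- rle(as.numeric(values))
  k <- length(r$lengths)
  if (k < 3) return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  i <- 2:(k - 1)
  is_max <- v[i] > v[i - 1] & v[i] > v[i + 1]
  is_min <- v[i] < v[i - 1] & v[i] < v[i + 1]
  list(maxima = starts[i][is_max], minima = starts[i][is_min])
}

#' Count zero-crossings
#'
#' Counts sign changes between consecutive nonzero values; a run of exact
#' zeros is one crossing only when the signs flanking the run differ.
#'
#' @param values numeric vector, length at least 2.
#' @return Nonnegative integer count.
#' @export
count_zero_crossings <- function(values) {
  if (length(values) < 2) stop("need at least 2 points")
  s <- sign(values)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# Mirror the extrema nearest each end across the end samples, then fit a
# natural cubic spline through the extended knots. Mirroring is the standard
# guard against envelope divergence at the boundaries, the known failure mode
# of spline envelopes.
extend_and_spline <- function(idx, values, n) {
  nl <- min(2L, length(idx))
  left  <- idx[seq_len(nl)]                       # nearest-to-start extrema
  right <- idx[seq(length(idx), by = -1L, length.out = nl)]
  xi <- c(2 - rev(left), idx, 2 * n - right)
  yi <- c(values[rev(left)], values[idx], values[right])
  keep <- !duplicated(xi)
  stats::splinefun(xi[keep], yi[keep], method = "natural")
}

#' Mean of the upper and lower spline envelopes
#'
#' Builds a natural cubic-spline upper envelope through the local maxima and a
#' lower envelope through the local minima (after mirror-extending the two
#' extrema nearest each end across the end point) and returns their pointwise
#' mean. For a true intrinsic mode function this mean is zero everywhere; its
#' repeated subtraction is one sifting round.
#'
#' @param values numeric vector.
#' @param maxima,minima extrema indices, normally from [find_extrema()];
#'   recomputed when missing.
#' @return Numeric vector of length `length(values)`, or `NULL` when the
#'   signal is not siftable (fewer than 2 maxima or 2 minima), in which case
#'   the caller should treat the current remainder as the residual.
#' @export
envelope_mean <- function(values, maxima = NULL, minima = NULL) {
  n <- length(values)
  if (is.null(maxima) || is.null(minima)) {
    ex <- find_extrema(values)
    maxima <- ex$maxima; minima <- ex$minima
  }
  if (length(maxima) < 2 || length(minima) < 2) return(NULL)
  up <- extend_and_spline(maxima, values, n)
  lo <- extend_and_spline(minima, values, n)
  t <- seq_len(n)
  (up(t) + lo(t)) / 2
}

#' Extract one intrinsic mode function by sifting
#'
#' Subtracts the envelope mean a fixed number of times (`h <- h -
#' envelope_mean(h)`). The fixed-count stoppage rule — 10 rounds by default —
#' guarantees a unique, reproducible decomposition, unlike Cauchy-type
#' convergence criteria whose output depends on a tolerance.
#'
#' @param values numeric vector (siftable: at least 2 maxima and 2 minima).
#' @param sift_iterations number of sifting rounds (default 10).
#' @return The sifted component. If the signal turns non-siftable mid-loop the
#'   current iterate is returned with attribute `incomplete = TRUE` and a
#'   warning.
#' @export
sift <- function(values, sift_iterations = 10L) {
  stopifnot(sift_iterations >= 1)
  h <- as.numeric(values)
  for (j in seq_len(sift_iterations)) {
    m <- envelope_mean(h)
    if (is.null(m)) {
      warning("signal became non-siftable after ", j - 1L, " iterations")
      attr(h, "incomplete") <- TRUE
      return(h)
    }
    h <- h - m
  }
  h
}

#' Empirical mode decomposition
#'
#' Adaptively decomposes a series into intrinsic mode functions (IMFs) plus a
#' residual: `X(t) = sum_j c_j(t) + r_N(t)`. IMFs are extracted from
#' successive remainders by [sift()]; extraction stops when the remainder has
#' fewer than 2 maxima or fewer than 2 minima, which then becomes the
#' residual. Reconstruction is exact up to floating-point error by
#' construction.
#'
#' @param x numeric vector or a [daily_series].
#' @param sift_iterations sifting rounds per IMF (default 10).
#' @param max_imfs optional cap on the number of IMFs (default unlimited).
#' @param boundary end-extension policy for envelopes; only `"mirror"` is
#'   implemented.
#' @return An object of class `emd`: list with `imfs` (n x N matrix, columns
#'   `imf1..imfN`), `residual`, `x` (the input values), `dates` (or `NULL`),
#'   `nimf`, `sift_iterations` and `method`.
#' @examples
#' t <- 0:1023
#' d <- emd(sin(2 * pi * t / 16) + 0.01 * t)
#' d$nimf
#' @export
emd <- function(x, sift_iterations = 10L, max_imfs = Inf,
                boundary = c("mirror")) {
  boundary <- match.arg(boundary)
  values <- as_values(x)
  dates <- as_dates(x)
  n <- length(values)
  if (n < 8) stop("series too short for envelope construction (need n >= 8)")
  r <- values
  comps <- list()
  repeat {
    ex <- find_extrema(r)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    if (length(comps) >= max_imfs) break
    c_j <- suppressWarnings(sift(r, sift_iterations))
    attributes(c_j) <- NULL
    comps[[length(comps) + 1L]] <- c_j
    r <- r - c_j
  }
  new_emd(comps, r, values, dates, sift_iterations, method = "emd")
}

new_emd <- function(comps, residual, x, dates, sift_iterations, method) {
  N <- length(comps)
  imfs <- if (N > 0) do.call(cbind, comps) else
    matrix(numeric(0), nrow = length(x), ncol = 0)
  if (N > 0) colnames(imfs) <- paste0("imf", seq_len(N))
  structure(list(imfs = imfs, residual = residual, x = x, dates = dates,
                 nimf = N, sift_iterations = sift_iterations,
                 method = method),
            class = "emd")
}

#' @export
print.emd <- function(x, ...) {
  cat("Empirical mode decomposition (", x$method, ")\n", sep = "")
  cat("  n = ", length(x$x), ", ", x$nimf, " IMFs + residual, ",
      x$sift_iterations, " sifting iterations\n", sep = "")
  err <- max(abs(x$x - fitted(x)))
  cat("  max reconstruction error: ", format(err, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
fitted.emd <- function(object, ...) {
  # element-wise sum of all components: reproduces the input
  if (object$nimf > 0) rowSums(object$imfs) + object$residual
  else object$residual
}

#' @export
residuals.emd <- function(object, ...) object$residual

#' Plot an empirical mode decomposition
#'
#' Stacked panels: the original series on top, each IMF below it, the residual
#' at the bottom — the conventional EMD display.
#'
#' @param x an `emd` object.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.emd <- function(x, ...) {
  N <- x$nimf
  t <- if (!is.null(x$dates)) x$dates else seq_along(x$x)
  op <- graphics::par(mfrow = c(N + 2, 1), mar = c(1.2, 4, 0.6, 1), oma = c(3, 0, 2, 0))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(t, x$x, type = "l", ylab = "X(t)", xaxt = "n", ...)
  for (j in seq_len(N))
    graphics::plot(t, x$imfs[, j], type = "l", ylab = paste0("IMF", j),
                   xaxt = "n", ...)
  graphics::plot(t, x$residual, type = "l", ylab = "residual", ...)
  graphics::mtext(paste0("EMD (", x$method, "), ", N, " IMFs"),
                  outer = TRUE, line = 0.5)
  invisible(x)
}

#' Write IMFs to a wide CSV
#'
#' Columns `date,imf1,...,imfN,residual`, full round-trip precision. A
#' decomposition of a plain numeric vector gets a synthetic 1-based `date`
#' index column.
#'
#' @param decomp an `emd` object.
#' @param path output path.
#' @export
write_imfs_csv <- function(decomp, path) {
  stopifnot(inherits(decomp, "emd"))
  date_col <- if (!is.null(decomp$dates)) format(decomp$dates)
              else seq_along(decomp$x)
  cols <- list(date = date_col)
  for (j in seq_len(decomp$nimf))
    cols[[paste0("imf", j)]] <- sprintf("%.17g", decomp$imfs[, j])
  cols$residual <- sprintf("%.17g", decomp$residual)
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read IMFs back from a wide CSV
#'
#' @param path CSV written by [write_imfs_csv()].
#' @return An `emd` object (with `x` reconstructed as the component sum).
#' @export
read_imfs_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  imf_cols <- grep("^imf[0-9]+$", names(raw), value = TRUE)
  if (!"residual" %in% names(raw)) stop(path, ": no residual column")
  imf_cols <- imf_cols[order(as.integer(sub("imf", "", imf_cols)))]
  comps <- lapply(imf_cols, function(cn) as.numeric(raw[[cn]]))
  residual <- as.numeric(raw$residual)
  dates <- suppressWarnings(as.Date(as.character(raw$date)))
  if (anyNA(dates)) dates <- NULL
  x <- Reduce(`+`, comps, residual)
  new_emd(comps, residual, x, dates, sift_iterations = NA_integer_,
          method = "from_file")
}
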