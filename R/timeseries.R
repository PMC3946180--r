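#' Daily time series
#'
#' Light container for a regularly sampled daily series: a data frame with a
#' `date` column (class `Date`, strictly increasing in 1-day steps, no gaps)
#' and a numeric `value` column. This is the currency every other function in
#' the package consumes and returns.
#'
#' @param dates `Date` vector (or something `as.Date()` accepts), one entry
#'   per day, strictly increasing with a constant 1-day step.
#' @param values numeric vector the same length as `dates`; no missing values.
#' @return An object of class `daily_series` (a data frame with columns
#'   `date` and `value`).
#' @examples
#' ds <- daily_series(seq(as.Date("2000-01-01"), by = "day", length.out = 30),
#'                    rnorm(30, 30, 5))
#' @export
daily_series <- function(dates, values) {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("`dates` and `values` must have the same length")
  validate_daily(dates, values)
  structure(data.frame(date = dates, value = values),
            class = c("daily_series", "data.frame"))
}

# shared validation; `where` prefixes error messages with a source (e.g. file)
validate_daily <- function(dates, values, where = NULL, min_n = 8L) {
  pre <- if (is.null(where)) "" else paste0(where, ": ")
  n <- length(dates)
  if (n < min_n)
    stop(pre, "need at least ", min_n, " daily observations, got ", n)
  if (anyNA(dates))
    stop(pre, "unparseable date at row ", which(is.na(dates))[1])
  d <- diff(as.integer(dates))
  if (any(d == 0))
    stop(pre, "duplicate date ", dates[which(d == 0)[1] + 1])
  if (any(d != 1))
    stop(pre, "gap in dates: ", dates[which(d != 1)[1]], " is followed by ",
         dates[which(d != 1)[1] + 1], " (expected the next calendar day)")
  if (anyNA(values))
    stop(pre, "missing/non-numeric value at row ", which(is.na(values))[1])
  invisible(TRUE)
}

#' @export
print.daily_series <- function(x, ...) {
  cat("Daily series: ", nrow(x), " days, ", format(x$date[1]), " to ",
      format(x$date[nrow(x)]), "\n", sep = "")
  cat("  mean ", format(mean(x$value), digits = 4), ", sd ",
      format(stats::sd(x$value), digits = 4), "\n", sep = "")
  invisible(x)
}

# coerce numeric / data.frame inputs to the pieces emd() needs
as_values <- function(x) {
  if (inherits(x, "daily_series") || (is.data.frame(x) && all(c("date", "value") %in% names(x))))
    return(as.numeric(x$value))
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a numeric vector or a daily series with columns date,value")
}

as_dates <- function(x) {
  if (is.data.frame(x) && "date" %in% names(x)) return(as.Date(x$date))
  NULL
}

#' Read a daily time series from CSV
#'
#' Expects a header `date,value`, ISO-8601 dates and one row per calendar day.
#' Any gap, duplicate date or non-numeric value is reported with the offending
#' row so malformed exports fail loudly rather than silently shifting windows.
#'
#' @param path path to a CSV file.
#' @return A [daily_series] object.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("date", "value") %in% names(raw)))
    stop(path, ": header must contain columns `date` and `value`")
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  suppressWarnings(values <- as.numeric(raw$value))
  bad <- which(is.na(values))
  if (length(bad))
    stop(path, ": non-numeric value '", raw$value[bad[1]], "' at row ", bad[1])
  validate_daily(dates, values, where = path)
  structure(data.frame(date = dates, value = values),
            class = c("daily_series", "data.frame"))
}

#' Write a daily time series to CSV
#'
#' Values are serialised with full round-trip precision (17 significant
#' digits) so that read-back reproduces them bit-exactly.
#'
#' @param x a [daily_series] (or data frame with `date`, `value`).
#' @param path output file path.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("date", "value") %in% names(x)))
  out <- data.frame(date = format(as.Date(x$date)),
                    value = sprintf("%.17g", x$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# parse "YYYY-MM-DD:YYYY-MM-DD" or a length-2 vector into an inclusive window
parse_window <- function(window) {
  if (is.character(window) && length(window) == 1 && grepl(":", window, fixed = TRUE))
    window <- strsplit(window, ":", fixed = TRUE)[[1]]
  if (length(window) != 2) stop("window must give a start and an end date")
  w <- as.Date(window)
  if (anyNA(w)) stop("unparseable window dates: ", paste(window, collapse = ", "))
  if (w[1] > w[2]) stop("window start ", w[1], " is after its end ", w[2])
  w
}
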