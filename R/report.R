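#' Write a JSON analysis report
#'
#' Serialises any of the package's result objects — a decomposition, a trend
#' partition, an excess-mortality fit, a regression, or a plain list — to a
#' JSON file, together with a configuration echo. Numeric content is written
#' at full precision; the report always records the seed when one was used
#' and a `generated` timestamp.
#'
#' @param results a result object or named list.
#' @param path output path (overwritten).
#' @param config optional named list echoed under `config`.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  body <- report_body(results)
  out <- c(list(generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           if (!is.null(config)) list(config = config),
           body)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

report_body <- function(x) {
  if (inherits(x, "hht_excess")) {
    list(method = x$method_used,
         seed = x$seed,
         m = x$partition$m,
         level = x$partition$level,
         noise_model = x$partition$mode,
         window = format(x$excess$window),
         excess_total = x$excess$total,
         excess_rounded = x$excess$rounded,
         daily = x$excess$daily,
         energies = unname(x$partition$spectrum$energies),
         model = unname(x$partition$spectrum$model),
         upper95 = unname(x$partition$spectrum$upper95),
         upper99 = unname(x$partition$spectrum$upper99),
         average_periods = unname(average_periods(x$decomposition)))
  } else if (inherits(x, "trend_partition")) {
    list(m = x$m, mode = x$mode, level = x$level,
         flagged = x$flagged,
         energies = unname(x$spectrum$energies),
         model = unname(x$spectrum$model),
         upper95 = unname(x$spectrum$upper95),
         upper99 = unname(x$spectrum$upper99),
         fitted_line = x$spectrum$fitted_line)
  } else if (inherits(x, "excess_lm")) {
    list(covariates = x$covariates, n = x$n,
         coefficients = cbind(term = rownames(x$coefficients),
                              x$coefficients),
         adj_r_squared = x$adj_r_squared)
  } else if (inherits(x, "emd")) {
    cfg <- attr(x, "eemd_config")
    c(list(method = x$method, nimf = x$nimf, n = length(x$x),
           sift_iterations = x$sift_iterations),
      if (!is.null(cfg)) cfg)
  } else if (is.list(x)) {
    x
  } else stop("cannot serialise object of class ", class(x)[1])
}
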