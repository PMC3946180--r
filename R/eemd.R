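#' Ensemble empirical mode decomposition
#'
#' Noise-assisted EMD: each trial decomposes the signal plus fresh Gaussian
#' white noise whose SD is `noise_factor` times the SD of the input, and the
#' ensemble mean of each component (aligned by order index, shorter
#' decompositions zero-padded to the largest number of components observed) is
#' returned. The added noise populates the time-frequency plane uniformly, so
#' intermittent bursts stop leaking across modes — the remedy for mode mixing.
#' Ensemble means are generally not exact IMFs; pass the result through
#' [post_process_eemd()] before Hilbert spectral analysis.
#'
#' @param x numeric vector or [daily_series].
#' @param ensemble_size number of noise-perturbed trials (default 100).
#' @param noise_factor added-noise SD as a fraction of `sd(x)` (default 0.1).
#' @param seed integer seed; required, every trial seed derives from it so the
#'   run is bit-reproducible.
#' @param sift_iterations,max_imfs passed to [emd()].
#' @return An `emd` object with `method = "eemd"`; carries the configuration
#'   as attribute `eemd_config`.
#' @export
eemd <- function(x, ensemble_size = 100L, noise_factor = 0.1, seed,
                 sift_iterations = 10L, max_imfs = Inf) {
  if (missing(seed) || is.null(seed)) stop("eemd() requires an integer `seed`")
  if (ensemble_size < 1) stop("ensemble_size must be at least 1")
  if (noise_factor < 0) stop("noise_factor must be nonnegative")
  values <- as_values(x)
  dates <- as_dates(x)
  sdx <- stats::sd(values)
  trial_seeds <- derive_seeds(seed, ensemble_size)

  trials <- vector("list", ensemble_size)
  for (i in seq_len(ensemble_size)) {
    noisy <- if (noise_factor > 0)
      values + gen_white_noise(length(values), sd = noise_factor * sdx,
                               seed = trial_seeds[i])
    else values
    trials[[i]] <- emd(noisy, sift_iterations = sift_iterations,
                       max_imfs = max_imfs)
  }
  out <- average_decompositions(trials, values, dates, sift_iterations,
                                method = "eemd")
  attr(out, "eemd_config") <- list(ensemble_size = ensemble_size,
                                   noise_factor = noise_factor, seed = seed)
  out
}

# element-wise mean of decompositions aligned by order index; shorter sets
# are padded with zero components
average_decompositions <- function(decomps, values, dates, sift_iterations,
                                   method) {
  Nmax <- max(vapply(decomps, function(d) d$nimf, integer(1)))
  n <- length(values)
  comps <- vector("list", Nmax)
  for (j in seq_len(Nmax)) {
    acc <- numeric(n)
    for (d in decomps)
      if (d$nimf >= j) acc <- acc + d$imfs[, j]
    comps[[j]] <- acc / length(decomps)
  }
  residual <- Reduce(`+`, lapply(decomps, function(d) d$residual)) /
    length(decomps)
  new_emd(comps, residual, values, dates, sift_iterations, method)
}

# reproducible sub-seed streams: a master seed deterministically yields
# distinct 31-bit seeds for trials/batches
derive_seeds <- function(seed, k) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Post-process ensemble-mean components into true IMFs
#'
#' Ensemble averaging breaks the strict IMF criteria. This sequential
#' re-sifting repairs them: the first IMF extracted from component k is kept
#' as final IMF k, the leftover of that inner decomposition is carried onto
#' component k+1 before it is processed, and the last carry joins the
#' residual. Conservation holds because carries are never dropped; components
#' whose carry-augmented signal is no longer siftable contribute a zero IMF,
#' which is pruned.
#'
#' @param components an `emd` object, normally from [eemd()].
#' @param sift_iterations sifting rounds for the inner extraction.
#' @return An `emd` object whose components satisfy the IMF construction.
#' @export
post_process_eemd <- function(components, sift_iterations = 10L) {
  stopifnot(inherits(components, "emd"))
  n <- length(components$x)
  N <- components$nimf
  carry <- numeric(n)
  finals <- list()
  for (k in seq_len(N)) {
    g <- components$imfs[, k] + carry
    ex <- find_extrema(g)
    if (length(ex$maxima) >= 2 && length(ex$minima) >= 2) {
      c1 <- suppressWarnings(sift(g, sift_iterations))
      attributes(c1) <- NULL
      finals[[length(finals) + 1L]] <- c1
      carry <- g - c1
    } else {
      # not siftable: whole component rides forward; zero IMF pruned here
      carry <- g
    }
  }
  residual <- components$residual + carry
  out <- new_emd(finals, residual, components$x, components$dates,
                 sift_iterations, method = paste0(components$method, "+pp"))
  attr(out, "eemd_config") <- attr(components, "eemd_config")
  out
}

#' Batch-averaged, post-processed EEMD
#'
#' The added white noise leaves some run-to-run fluctuation in a single EEMD
#' decomposition. Running `batches` independent EEMD + post-processing passes
#' (each from a sub-seed derived from `seed`) and averaging the aligned
#' results damps that fluctuation; 20 batches is the default.
#'
#' @inheritParams eemd
#' @param batches number of EEMD + post-processing passes to average.
#' @return An `emd` object with `method = "eemd_batch"`.
#' @export
batch_eemd <- function(x, batches = 20L, ensemble_size = 100L,
                       noise_factor = 0.1, seed, sift_iterations = 10L,
                       max_imfs = Inf) {
  if (missing(seed) || is.null(seed)) stop("batch_eemd() requires `seed`")
  if (batches < 1) stop("batches must be at least 1")
  values <- as_values(x)
  dates <- as_dates(x)
  batch_seeds <- derive_seeds(seed + 1L, batches)
  runs <- vector("list", batches)
  for (b in seq_len(batches)) {
    e <- eemd(values, ensemble_size = ensemble_size,
              noise_factor = noise_factor, seed = batch_seeds[b],
              sift_iterations = sift_iterations, max_imfs = max_imfs)
    runs[[b]] <- post_process_eemd(e, sift_iterations)
  }
  out <- average_decompositions(runs, values, dates, sift_iterations,
                                method = "eemd_batch")
  attr(out, "eemd_config") <- list(ensemble_size = ensemble_size,
                                   noise_factor = noise_factor,
                                   batches = batches, seed = seed)
  out
}
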