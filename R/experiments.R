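# Validation experiments: the simulation studies that establish the method's
# operating characteristics (reconstruction fidelity, the white-noise energy
# law, significance-test calibration and power, the dyadic filter bank,
# spike-mass recovery, regression recovery, and the ensemble remedy for mode
# mixing). Each experiment derives all of its randomness from one master
# seed, so the test suite and the acceptance script run the identical study
# at different seeds. Internal: not part of the user API.

# the white-noise replicate bank is shared by three experiments; cache per
# (seed, size) within a session
.experiment_cache <- new.env(parent = emptyenv())

# 200 EMDs of N(0,1) noise, n = 4096: per-replicate mode energies and periods
exp_noise_bank <- function(master_seed, n_rep = 200, n = 4096) {
  key <- paste("bank", master_seed, n_rep, n, sep = "_")
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  seeds <- derive_seeds(master_seed + 11L, n_rep)
  energies <- vector("list", n_rep)
  periods <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    d <- emd(gen_white_noise(n, seed = seeds[r]))
    energies[[r]] <- unname(imf_energies(d))
    periods[[r]] <- unname(average_periods(d))
  }
  .experiment_cache[[key]] <- list(energies = energies, periods = periods,
                                   n_rep = n_rep, n = n)
  .experiment_cache[[key]]
}

# worked six-day window sum (deterministic)
exp_table1 <- function() {
  vals <- c(5.7, 6.7, 7.6, -0.4, 20.6, 11.6)
  dates <- seq(as.Date("2004-02-18"), by = "day", length.out = 6)
  excess_deaths(vals, c("2004-02-18", "2004-02-23"), dates = dates)
}

# worst relative reconstruction error over heterogeneous inputs
exp_reconstruction <- function(master_seed, n_cases = 100) {
  seeds <- derive_seeds(master_seed + 21L, n_cases)
  worst <- 0
  for (i in seq_len(n_cases)) {
    n <- if (i %% 2 == 0) 256 else 2922
    t <- 0:(n - 1)
    x <- switch((i %% 4) + 1,
      gen_white_noise(n, sd = 5, seed = seeds[i]),
      gen_white_noise(n, seed = seeds[i]) + 0.01 * t,
      3 * sin(2 * pi * t / 20) + 0.5 * t / n +
        gen_white_noise(n, seed = seeds[i]),
      30 + 3 * cos(2 * pi * t / 365.25) +
        gen_white_noise(n, sd = 5, seed = seeds[i]))
    d <- emd(x)
    worst <- max(worst, max(abs(x - fitted(d))) / max(abs(x)))
  }
  worst
}

# OLS slope of mean log2 energy against mode index, k = 2..7
exp_energy_slope <- function(bank) {
  Emat <- t(vapply(bank$energies, function(e) e[1:7], numeric(7)))
  mean_log2 <- log2(colMeans(Emat))
  k <- 2:7
  unname(stats::coef(stats::lm(mean_log2[k] ~ k))[2])
}

# fraction of pure-noise replicates with no trend flag at the 99% band
exp_calibration <- function(bank) {
  no_flag <- vapply(bank$energies, function(E) {
    k <- 2:length(E)
    upper <- log2(white_noise_energy_model(E[1], length(E))) +
      2^(0.460 * k - 1.919)
    !any(log2(E[k]) > upper)
  }, logical(1))
  mean(no_flag)
}

# fraction of replicates in which a 5-sigma annual cycle is flagged as trend
exp_power_annual <- function(master_seed, n_rep = 100, n = 2922) {
  seeds <- derive_seeds(master_seed + 31L, n_rep)
  hits <- vapply(seq_len(n_rep), function(r) {
    x <- gen_white_noise(n, seed = seeds[r]) +
      5 * sin(2 * pi * (0:(n - 1)) / 365.25)
    d <- emd(x)
    p <- classify_trend(d, level = 99, mode = "white")
    per <- average_periods(d)
    annual <- which(!is.na(per) & per >= 250 & per <= 500)
    length(annual) > 0 && any(annual %in% p$flagged)
  }, logical(1))
  mean(hits)
}

# pooled median ratio of consecutive mode periods over noise replicates
exp_dyadic <- function(bank, n_rep = 100) {
  ratios <- unlist(lapply(bank$periods[seq_len(n_rep)], function(p) {
    p <- p[!is.na(p)]
    p[-1] / p[-length(p)]
  }))
  stats::median(ratios)
}

# full-pipeline spike-mass recovery on the default 8-year scenario
exp_recovery <- function(master_seed, n_seeds = 50) {
  seeds <- derive_seeds(master_seed + 41L, n_seeds)
  totals <- vapply(seeds, function(s) {
    sim <- gen_mortality(mortality_scenario(seed = s))
    fit <- hht_excess(sim$mortality, window = c("2004-02-18", "2004-02-23"),
                      method = "emd")
    fit$excess$total
  }, numeric(1))
  list(totals = totals, rate = mean(abs(totals - 50) <= 15))
}

# 2-SE coverage of a known temperature-anomaly slope over a 91-day window
exp_regression <- function(master_seed, n_seeds = 100) {
  sa <- derive_seeds(master_seed + 51L, n_seeds)
  sb <- derive_seeds(master_seed + 61L, n_seeds)
  hits <- vapply(seq_len(n_seeds), function(r) {
    anom <- 2 * gen_correlated_noise(91, "ar1", 0.6, seed = sa[r])
    lr <- 0.06 * anom + gen_white_noise(91, sd = 0.15, seed = sb[r])
    f <- fit_excess_regression(data.frame(logRR = lr, maxT_non_trend = anom),
                               "maxT_non_trend")
    abs(stats::coef(f)["maxT_non_trend"] - 0.06) <=
      2 * f$coefficients["maxT_non_trend", "std_error"]
  }, logical(1))
  mean(hits)
}

# how often the post-processed ensemble's first component tracks the burst
# better than plain EMD's first mode on the intermittency fixture
exp_mode_mixing <- function(master_seed, n_seeds = 20, ensemble_size = 100) {
  fx <- gen_intermittent()
  d <- emd(fx$series)
  cor_emd <- stats::cor(d$imfs[, 1], fx$burst)
  seeds <- derive_seeds(master_seed + 71L, n_seeds)
  wins <- vapply(seeds, function(s) {
    e <- post_process_eemd(eemd(fx$series, ensemble_size = ensemble_size,
                                seed = s))
    stats::cor(e$imfs[, 1], fx$burst) > cor_emd
  }, logical(1))
  e0 <- eemd(fx$series, ensemble_size = 1, noise_factor = 0, seed = 1)
  list(win_rate = mean(wins),
       degenerate_identical = identical(unname(e0$imfs), unname(d$imfs)) &&
         identical(e0$residual, d$residual))
}

# worst interior deviation of a 20-day tone's instantaneous frequency from
# 0.05 cycles/day
exp_tone_frequency <- function() {
  sp <- instantaneous_spectrum(sin(2 * pi * (0:799) / 20), dt = 1)
  max(abs(sp$frequency[sp$valid] - 0.05))
}
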