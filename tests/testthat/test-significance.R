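test_that("mode energies are raw sums of squares", {
  d <- emd(gen_white_noise(256, seed = 1))
  # quadratic form: doubling a mode quadruples its energy
  E <- imf_energies(d)
  expect_equal(unname(E[1]), sum(d$imfs[, 1]^2))
  d2 <- d
  d2$imfs[, 1] <- 2 * d2$imfs[, 1]
  expect_equal(unname(imf_energies(d2)[1]), 4 * unname(E[1]))

  fake <- d
  fake$imfs[, 1] <- c(1, 2, 2, rep(0, 253))
  expect_equal(unname(imf_energies(fake)[1]), 9)
  fake$imfs[, 2] <- 0
  expect_equal(unname(imf_energies(fake)[2]), 0)
})

test_that("the white-noise energy model decays geometrically at rate 2.01", {
  w <- white_noise_energy_model(0.719, 9)
  expect_equal(unname(w[1]), 2.01^-2)          # k = 2 ordinate
  ratios <- w[-1] / w[-length(w)]
  expect_equal(unname(ratios), rep(1 / 2.01, length(ratios)))
  # exactly linear in log2 with slope -log2(2.01)
  k <- 2:9
  fit <- lm(log2(w) ~ k)
  expect_equal(unname(coef(fit)[2]), -log2(2.01), tolerance = 1e-10)
  expect_error(white_noise_energy_model(0, 5), "positive")
})

test_that("confidence-band margins match their closed forms and orderings", {
  w <- white_noise_energy_model(1, 12)
  b <- confidence_bands(w)
  k <- 2:12
  expect_equal(unname(b$upper95 - log2(w)), 2^(0.474 * k - 2.449))
  expect_equal(unname(b$upper95[1] - log2(w[1])), 2^-1.501)
  # margins strictly increase with k; 99% band above 95% throughout k = 2..12
  expect_true(all(diff(b$upper95 - log2(w)) > 0))
  expect_true(all(b$upper99 > b$upper95))
})

test_that("pure noise is rarely flagged and a strong annual cycle always is", {
  flagged <- 0L
  for (s in 1:30) {
    p <- classify_trend(emd(gen_white_noise(2048, seed = 300 + s)),
                        level = 99, mode = "white")
    if (length(p$flagged)) flagged <- flagged + 1L
  }
  expect_lte(flagged / 30, 0.3)

  hits <- 0L
  for (s in 1:10) {
    n <- 2922
    x <- gen_white_noise(n, seed = 400 + s) +
      5 * sin(2 * pi * (0:(n - 1)) / 365.25)
    d <- emd(x)
    p <- classify_trend(d, level = 99, mode = "white")
    per <- average_periods(d)
    annual <- which(!is.na(per) & per >= 250 & per <= 500)
    if (length(annual) && any(annual %in% p$flagged)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("auto mode switches to the generalized test under serial correlation", {
  pick <- sapply(1:30, function(s) {
    x <- gen_correlated_noise(2048, "ar1", 0.5, seed = 500 + s)
    classify_trend(emd(x), mode = "auto")$mode
  })
  expect_gt(mean(pick == "generalized"), 0.5)

  # and stays white on white noise
  pick_w <- sapply(1:15, function(s) {
    classify_trend(emd(gen_white_noise(2048, seed = 600 + s)),
                   mode = "auto")$mode
  })
  expect_gt(mean(pick_w == "white"), 0.5)
})

test_that("the partition is contiguous, complete, and nests across band levels", {
  for (s in 1:10) {
    d <- emd(smooth_noise_series(1024, seed = 700 + s, trend_scale = 4))
    p95 <- classify_trend(d, level = 95)
    p99 <- classify_trend(d, level = 99)
    N <- d$nimf
    expect_setequal(c(p95$non_trend_indices, p95$trend_indices), seq_len(N))
    # IMF 1 anchors the model and is never trend
    expect_true(1 %in% p95$non_trend_indices)
    # tightening 99 -> 95 never unflags: m can only shrink
    expect_lte(p95$m, p99$m)
  }
})

test_that("too few modes is an error", {
  d <- emd(make_tone(128, 16))
  expect_lte(d$nimf, 2)
  expect_error(classify_trend(d), "too few IMFs")
})

test_that("emd/eemd tests agree on clean series and break on spiky correlated ones", {
  # mixing-free: annual cycle + white noise, the clean-decomposition scenario
  t <- 0:1459
  clean_agree <- sapply(1:6, function(s) {
    x <- 30 + 5 * cos(2 * pi * t / 365.25) +
      gen_white_noise(1460, sd = 1, seed = 80 + s)
    emd_eemd_agreement(x, seed = 5, level = 99, ensemble_size = 20,
                       batches = 2)$agreement
  })
  expect_gte(mean(clean_agree), 0.8)

  # a huge spike on serially correlated noise disrupts the agreement far
  # more often: the diagnostic that signals the ensemble variant is needed
  spike_agree <- sapply(1:6, function(s) {
    sc <- mortality_scenario(n = 1460, start_date = "1996-07-01",
                             baseline = 115, seasonal_amplitude = 10,
                             noise_kind = "ar1",
                             noise_params = list(sd = 12, phi = 0.5),
                             heatwaves = list(list(start = "1998-07-11",
                                                   end = "1998-07-16",
                                                   mass = 500,
                                                   shape = "triangular")),
                             seed = 600 + s)
    sim <- gen_mortality(sc)
    emd_eemd_agreement(sim$mortality, seed = 5, level = 99,
                       ensemble_size = 20, batches = 2)$agreement
  })
  expect_gt(sum(!spike_agree), sum(!clean_agree))

  # determinism of the whole report
  x <- 30 + 5 * cos(2 * pi * t / 365.25) +
    gen_white_noise(1460, sd = 1, seed = 81)
  rep1 <- emd_eemd_agreement(x, seed = 5, ensemble_size = 10, batches = 2)
  rep2 <- emd_eemd_agreement(x, seed = 5, ensemble_size = 10, batches = 2)
  expect_identical(rep1$m_eemd, rep2$m_eemd)
  expect_identical(rep1$agreement, rep2$agreement)
  expect_identical(rep1$decomp_eemd$imfs, rep2$decomp_eemd$imfs)
})

test_that("sample autocorrelations come with the 1.96/sqrt(n) band", {
  a <- acf_bands(gen_white_noise(2000, seed = 3), max_lag = 10)
  expect_equal(a$acf[1], 1)
  expect_equal(attr(a, "band"), 1.96 / sqrt(2000))

  # white-noise calibration: lag-1 within the band in roughly 95% of runs
  inside <- sapply(1:100, function(s) {
    a <- acf_bands(gen_white_noise(500, seed = 800 + s), max_lag = 1)
    abs(a$acf[2]) < 1.96 / sqrt(500)
  })
  expect_gte(mean(inside), 0.88)

  # AR(1) population value phi^1
  a5 <- acf_bands(gen_correlated_noise(5000, "ar1", 0.5, seed = 9), max_lag = 2)
  expect_gte(a5$acf[2], 0.45)
  expect_lte(a5$acf[2], 0.55)
  expect_error(acf_bands(gen_white_noise(50, seed = 1), max_lag = 50), "max_lag")
})
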