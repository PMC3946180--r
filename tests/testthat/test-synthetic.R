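test_that("white noise has the requested moments and is seed-deterministic", {
  x <- gen_white_noise(2000, sd = 3, seed = 1)
  expect_lte(abs(mean(x)), 4 * 3 / sqrt(2000))
  expect_lte(abs(sd(x) - 3) / 3, 0.1)
  expect_identical(x, gen_white_noise(2000, sd = 3, seed = 1))
  expect_false(identical(x, gen_white_noise(2000, sd = 3, seed = 2)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(1)
  set.seed(99)
  invisible(gen_white_noise(10, seed = 5))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("AR(1) noise matches its population autocorrelation", {
  x <- gen_correlated_noise(5000, "ar1", 0.5, seed = 3)
  r1 <- acf_bands(x, 1)$acf[2]
  expect_gte(r1, 0.45)
  expect_lte(r1, 0.55)
  expect_lte(abs(sd(x) - 1), 0.1)
  expect_error(gen_correlated_noise(100, "ar1", 1.2, seed = 1), "phi")
})

test_that("fractional noise reduces to white at H = 0.5 and is persistent at H = 0.8", {
  inside <- sapply(1:40, function(s) {
    x <- gen_correlated_noise(1000, "fgn", 0.5, seed = 100 + s)
    abs(acf_bands(x, 1)$acf[2]) < 1.96 / sqrt(1000)
  })
  expect_gte(mean(inside), 0.85)

  # population lag-1 autocorrelation 2^(2H-1) - 1 ~= 0.516 at H = 0.8
  x <- gen_correlated_noise(4096, "fgn", 0.8, seed = 7)
  r1 <- acf_bands(x, 1)$acf[2]
  expect_gte(r1, 0.4)
  expect_lte(r1, 0.65)
  expect_lte(abs(sd(x) - 1), 0.15)
  expect_error(gen_correlated_noise(100, "fgn", 1.5, seed = 1), "0 < H < 1")
})

test_that("a noise-free scenario is the closed-form deterministic signal", {
  sc <- mortality_scenario(n = 800, seasonal_amplitude = 0, trend_slope = 0,
                           heatwaves = list(), seed = 1)
  # zero out the stochastic term by construction: sd -> tiny
  sc$noise_params$sd <- 1e-12
  sim <- gen_mortality(sc)
  expect_equal(sim$mortality$value, rep(30, 800), tolerance = 1e-9)

  sc2 <- mortality_scenario(n = 800, seed = 1,
                            heatwaves = list(list(start = "1997-02-01",
                                                  end = "1997-02-06",
                                                  mass = 50,
                                                  shape = "rectangular")))
  sc2$noise_params$sd <- 1e-12
  sc2$seasonal_amplitude <- 0
  sc2$trend_slope <- 0
  sim2 <- gen_mortality(sc2)
  widx <- which(sim2$mortality$date >= as.Date("1997-02-01") &
                  sim2$mortality$date <= as.Date("1997-02-06"))
  expect_equal(sim2$mortality$value[widx], rep(30 + 50 / 6, 6),
               tolerance = 1e-9)
})

test_that("truth records book-keep the injected spike mass exactly", {
  sim <- gen_mortality(small_scenario(seed = 2, mass = 50))
  ev <- sim$truth$events[[1]]
  expect_equal(ev$window_sum, 50)
  expect_equal(sum(sim$truth$spikes), 50)
  # and the linked temperature anomaly is elevated exactly over the window
  widx <- which(sim$mortality$date >= ev$start & sim$mortality$date <= ev$end)
  expect_true(all(sim$truth$maxT_anomaly[widx] > 0))
  expect_true(all(sim$truth$maxT_anomaly[-widx] == 0))
})

test_that("scenario validation rejects out-of-range windows and bad noise", {
  expect_error(mortality_scenario(n = 100, heatwaves = list(
    list(start = "2004-02-18", end = "2004-02-23", mass = 50,
         shape = "triangular"))), "outside")
  expect_error(mortality_scenario(noise_params = list(sd = -1)), "positive")
})

test_that("negative mortality is clipped with a warning and flagged", {
  sc <- mortality_scenario(n = 400, baseline = 2, seasonal_amplitude = 0,
                           heatwaves = list(), noise_params = list(sd = 5),
                           seed = 8)
  expect_warning(sim <- gen_mortality(sc), "clipped")
  expect_true(any(sim$truth$clipped))
  expect_true(all(sim$mortality$value >= 0))
})

test_that("poisson noise gives integer counts", {
  sc <- mortality_scenario(n = 400, noise_kind = "poisson",
                           heatwaves = list(), seed = 3)
  sim <- gen_mortality(sc)
  expect_true(all(sim$mortality$value == round(sim$mortality$value)))
})

test_that("the intermittency fixture mixes modes under plain EMD", {
  fx <- gen_intermittent()
  # zero-amplitude bursts leave the pure carrier
  fx0 <- gen_intermittent(amplitudes = c(1, 0))
  expect_equal(fx0$series, fx0$carrier)

  # mixing symptom: IMF1 follows the carrier outside the burst windows
  d <- emd(fx$series)
  non_burst <- which(fx$burst == 0)
  expect_gt(abs(cor(d$imfs[non_burst, 1], fx$carrier[non_burst])), 0.3)
  expect_error(gen_intermittent(burst_period = 200, carrier_period = 100),
               "shorter")
})

test_that("ensemble averaging separates the burst scale better than plain EMD", {
  fx <- gen_intermittent()
  d <- emd(fx$series)
  cor_emd <- cor(d$imfs[, 1], fx$burst)
  wins <- sapply(1:5, function(s) {
    e <- post_process_eemd(eemd(fx$series, ensemble_size = 50, seed = s))
    cor(e$imfs[, 1], fx$burst) > cor_emd
  })
  expect_gte(mean(wins), 0.6)
})
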