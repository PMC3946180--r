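test_that("partitioning splits modes contiguously and conserves the series", {
  x <- gen_white_noise(512, seed = 2)
  d <- emd(x)
  N <- d$nimf
  # m = N-1: trend is last mode plus residual, by definition
  ps <- partition_series(d, N - 1)
  expect_equal(ps$trend, d$imfs[, N] + d$residual)
  expect_lte(max(abs(ps$non_trend + ps$trend - x)), 1e-8 * max(abs(x)))
  expect_error(partition_series(d, 0), "outside")
  expect_error(partition_series(d, N + 1), "outside")
})

test_that("the heatwave spike lands in the detail series", {
  sim <- gen_mortality(small_scenario(seed = 3))
  d <- emd(sim$mortality)
  p <- classify_trend(d, level = 99)
  ps <- partition_series(d, p)
  widx <- which(sim$mortality$date >= as.Date("1999-02-18") &
                  sim$mortality$date <= as.Date("1999-02-23"))
  # window mean far exceeds the background detail level
  expect_gt(mean(ps$non_trend[widx]), 1)
  expect_gt(mean(ps$non_trend[widx]), 10 * abs(mean(ps$non_trend[-widx])))
})

test_that("window excess sums use inclusive dates and round half away from zero", {
  vals <- c(5.7, 6.7, 7.6, -0.4, 20.6, 11.6)
  dates <- seq(as.Date("2004-02-18"), by = "day", length.out = 6)
  r <- excess_deaths(vals, c("2004-02-18", "2004-02-23"), dates = dates)
  expect_equal(r$total, 51.8)
  expect_identical(r$rounded, 52L)
  expect_identical(nrow(r$daily), 6L)

  # half-away-from-zero on both signs
  expect_identical(hhtexcess:::round_half_away(2.5), 3L)
  expect_identical(hhtexcess:::round_half_away(-2.5), -3L)

  expect_error(excess_deaths(vals, c("2004-03-01", "2004-03-05"),
                             dates = dates), "outside")
})

test_that("the full-record detail sum is near zero", {
  x <- gen_white_noise(2048, seed = 6) + 30
  d <- emd(x)
  p <- classify_trend(d)
  ps <- partition_series(d, p)
  total <- excess_deaths(ps$non_trend, c(1L, 2048L))$total
  expect_lte(abs(total), 0.02 * sum(abs(x)))
})

test_that("log relative risk handles exact ratios, zeros, and bad trends", {
  trend <- rep(10, 20)
  expect_equal(log_relative_risk(trend, trend), rep(0, 20))
  expect_equal(log_relative_risk(exp(1) * trend, trend), rep(1, 20))

  x <- trend; x[5] <- 0
  expect_warning(lr <- log_relative_risk(x, trend), "-Inf")
  expect_identical(lr[5], -Inf)
  lr2 <- log_relative_risk(x, trend, zero_correction = TRUE)
  expect_equal(lr2[5], log(0.5 / 10))

  bad <- trend; bad[7] <- -1
  expect_error(log_relative_risk(x, bad), "strictly positive")
})

test_that("excess regression recovers exact and noisy slopes and flags bad designs", {
  # noiseless linear relation: exact coefficient, adjusted R^2 = 1
  x <- seq(20, 40, length.out = 30)
  dat <- data.frame(logRR = 0.05 * x, maxT = x)
  # the noiseless design triggers R's perfect-fit note; that is the point
  fit <- suppressWarnings(fit_excess_regression(dat, "maxT"))
  expect_equal(unname(coef(fit)["maxT"]), 0.05, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1)

  # permuted response: no explanatory power
  set.seed(15)
  dat2 <- data.frame(logRR = rnorm(91), maxT = rnorm(91))
  fit2 <- fit_excess_regression(dat2, "maxT")
  expect_lte(abs(fit2$adj_r_squared), 0.1)

  # parameter recovery: estimate within 2 SE of the truth in >= 90% of seeds
  hits <- sapply(1:30, function(s) {
    anom <- gen_correlated_noise(91, "ar1", 0.6, seed = 900 + s) * 2
    lr <- 0.06 * anom + gen_white_noise(91, sd = 0.15, seed = 950 + s)
    f <- fit_excess_regression(data.frame(logRR = lr, maxT_non_trend = anom),
                               "maxT_non_trend")
    abs(coef(f)["maxT_non_trend"] - 0.06) <=
      2 * f$coefficients["maxT_non_trend", "std_error"]
  })
  expect_gte(mean(hits), 0.9)

  # collinear design is rejected
  dat3 <- data.frame(logRR = rnorm(20), a = 1:20, b = 2 * (1:20))
  expect_error(fit_excess_regression(dat3, c("a", "b")), "rank-deficient")
  expect_error(fit_excess_regression(dat2[1:3, ], "maxT"), "at least")
})

test_that("regressions can be restricted to a date window", {
  dates <- seq(as.Date("2003-12-01"), by = "day", length.out = 120)
  dat <- data.frame(date = dates, logRR = rnorm(120), maxT = rnorm(120))
  fit <- fit_excess_regression(dat, "maxT",
                               window = c("2003-12-01", "2004-02-29"))
  expect_identical(fit$n, 91L)
})

test_that("classical decomposition has the textbook window geometry", {
  n <- 1461   # 4 years
  t <- 0:(n - 1)
  x <- 10 * sin(2 * pi * t / 365) + 30
  cl <- classical_decompose(x, frequency = 365)
  # trend undefined for exactly floor(365/2) points at each end
  expect_identical(which(!is.na(cl$trend))[1], 183L)
  expect_identical(sum(is.na(cl$trend)), 2L * 182L)
  # a pure 365-periodic signal is recovered by the seasonal component
  ok <- !is.na(cl$random)
  expect_gte(cor(cl$seasonal[ok], (x - 30)[ok]), 0.99)
  expect_lte(max(abs(cl$random[ok])), 0.5)
  # conservation where defined
  expect_equal(cl$trend[ok] + cl$seasonal[ok] + cl$random[ok], x[ok])
  expect_error(classical_decompose(x[1:600]), "two full cycles")
})

test_that("the adaptive detail covers record ends the moving average cannot", {
  # spike in the final 90 days: classical random is NA there, detail is not
  n <- 1096
  sc <- mortality_scenario(n = n, start_date = "1996-07-01",
                           heatwaves = list(list(start = "1999-05-20",
                                                 end = "1999-05-25",
                                                 mass = 50,
                                                 shape = "triangular")),
                           seed = 31)
  sim <- gen_mortality(sc)
  widx <- which(sim$mortality$date >= as.Date("1999-05-20") &
                  sim$mortality$date <= as.Date("1999-05-25"))
  cl <- classical_decompose(sim$mortality, frequency = 365)
  expect_true(all(is.na(cl$random[widx])))
  d <- emd(sim$mortality)
  ps <- partition_series(d, classify_trend(d))
  expect_true(all(is.finite(ps$non_trend[widx])))
})

test_that("trend side keeps the mean level, detail is mean-zero", {
  sim <- gen_mortality(small_scenario(seed = 12))
  x <- sim$mortality$value
  d <- emd(x)
  ps <- partition_series(d, classify_trend(d))
  expect_lte(abs(mean(ps$trend) - mean(x)), 0.02 * mean(x))
  expect_lte(abs(mean(ps$non_trend)), 0.02 * mean(x))
})

test_that("temperature anomaly selection matches scales or falls back to m", {
  sim <- gen_mortality(small_scenario(seed = 16))
  d <- emd(sim$mortality)
  p <- classify_trend(d)
  an <- temperature_anomaly(sim$maxT, d, p)
  expect_length(an$anomaly, nrow(sim$maxT))
  expect_gte(an$m_temp, 1)
  expect_lte(an$m_temp, an$decomp$nimf)
  # anomaly is a detail series: mean near zero relative to the temperature level
  expect_lte(abs(mean(an$anomaly)), 0.05 * mean(sim$maxT$value))
})

test_that("the end-to-end pipeline estimates a plausible spike mass", {
  sim <- gen_mortality(small_scenario(seed = 4))
  fit <- hht_excess(sim$mortality, window = c("1999-02-18", "1999-02-23"),
                    method = "emd")
  expect_s3_class(fit, "hht_excess")
  expect_gt(fit$excess$total, 20)
  expect_lt(fit$excess$total, 80)
  expect_identical(fit$excess$rounded,
                   hhtexcess:::round_half_away(fit$excess$total))
  expect_equal(fitted(fit) + residuals(fit), sim$mortality$value,
               tolerance = 1e-8)
  expect_output(print(fit), "excess deaths")
  expect_output(print(summary(fit)), "Average periods")
})
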