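# Fixtures built in code: tones, noise-plus-trend series, and scaled-down
# mortality scenarios used across the module tests.

make_tone <- function(n, period, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * (0:(n - 1)) / period + phase)
}

# smooth slow trend + white noise: the mode-mixing-free scenario
smooth_noise_series <- function(n = 1024, seed = 1, trend_scale = 3,
                                noise_sd = 1) {
  t <- 0:(n - 1)
  trend <- trend_scale * sin(2 * pi * t / (n / 1.5))
  trend + gen_white_noise(n, sd = noise_sd, seed = seed)
}

# 3-year mortality scenario with a February heatwave in the final year;
# small enough for repeated decomposition in unit tests
small_scenario <- function(seed, n = 1096, mass = 50) {
  mortality_scenario(n = n, start_date = "1996-07-01",
                     heatwaves = list(list(start = "1999-02-18",
                                           end = "1999-02-23",
                                           mass = mass,
                                           shape = "triangular")),
                     seed = seed)
}
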