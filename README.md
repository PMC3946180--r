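# hhtexcess

Heatwave excess mortality from daily death counts via the Hilbert–Huang
Transform (HHT).

## The problem

Excess mortality during an event (a heatwave, an epidemic wave) is the sum of
observed deaths minus the deaths expected under "normal" conditions over the
event window. Estimating the normal level is hard because daily mortality
series are non-stationary (slowly drifting mean levels) and nonlinearly
coupled to temperature: moving averages blur local features and lose both
record ends, and smoothing splines hinge on an arbitrary smoothing parameter.

## The method

**Empirical mode decomposition (EMD).** The series is decomposed adaptively
into intrinsic mode functions (IMFs) plus a residual,

    X(t) = Σⱼ cⱼ(t) + r_N(t),

by sifting: each candidate component repeatedly has the mean of its upper and
lower cubic-spline extrema envelopes subtracted (a fixed 10 iterations, which
makes the decomposition unique). IMFs come out ordered fine to coarse.

**Energy significance test.** For Gaussian white noise the expected mode
energies `E_k = Σᵢ d_k(i)²` follow the geometric law

    W_Hk = (E₁ / 0.719) · 2.01⁻ᵏ,   k = 2, …, N,

a straight line of slope −log₂ 2.01 ≈ −1.007 in log₂-energy versus mode
index, with upper confidence ordinates
`upper95[k] = log₂ W_Hk + 2^(0.474k − 2.449)` and
`upper99[k] = log₂ W_Hk + 2^(0.460k − 1.919)`. Modes whose observed log₂
energy rises above the band are *trend*; the low-order modes below it are
*non-trend* (noise-like detail). For serially correlated noise the line is
replaced by a least-squares fit through the first few modes (the generalized
test). Writing `m` for the split,

    X(t) = Σᵢ₌₁ᵐ cᵢ(t)  +  [ Σⱼ₌ₘ₊₁ᴺ cⱼ(t) + r_N(t) ],
           └─ detail ─┘     └────────── trend ──────────┘

the excess mortality over a window is simply the window sum of the detail
series, and the daily log relative risk is `log RR(t) = ln X(t)/trend(t)`.

**Ensemble EMD (EEMD).** Intermittent spikes cause mode mixing (one mode
carrying disparate time scales). EEMD decomposes many noise-perturbed copies
(default 100 trials at 0.1 SD added noise) and averages them, followed by a
post-processing pass that restores exact IMFs and a batch average (default
20) that damps the residual ensemble randomness. Running the significance
test on both EMD and EEMD output and comparing the partitions diagnoses
whether plain EMD suffices.

## Worked example

```r
library(hhtexcess)

# 8 years of synthetic subtropical daily mortality (baseline 30 deaths/day,
# annual cycle, white noise SD 5) with a 6-day heatwave adding 50 deaths
sim <- gen_mortality(mortality_scenario(seed = 7))

fit <- hht_excess(sim$mortality, window = c("2004-02-18", "2004-02-23"),
                  method = "emd")
fit
#> Heatwave excess mortality (Hilbert-Huang decomposition)
#>   method: emd; non-trend modes: 1..4 of 9 (white noise model, 95% band)
#>   window 2004-02-18 .. 2004-02-23 (6 days)
#>   excess deaths: 36.87 (rounded: 37)

round(average_periods(fit$decomposition), 1)
#>   imf1   imf2   imf3   imf4   imf5   imf6   imf7   imf8   imf9
#>    2.9    5.9   11.8   23.4   48.7   85.9  292.2  730.5 1461.0
```

The decomposition found 9 IMFs whose average periods roughly double from
mode to mode (the dyadic filter-bank signature); modes 1–4 were classified
non-trend, and their sum over the 6-day window estimates the heatwave's
excess mortality at ~37 deaths against an injected 50 — the injected mass
minus the smearing and window-noise effects discussed in the vignette.
`fitted(fit)` returns the trend ("normal conditions") series and
`residuals(fit)` the daily excess series.

Excess-risk regression against the EMD temperature anomaly over the 91-day
summer:

```r
an  <- temperature_anomaly(sim$maxT, fit$decomposition, fit$partition)
dat <- data.frame(date = sim$mortality$date, logRR = fit$logRR,
                  maxT_non_trend = an$anomaly)
fit_excess_regression(dat, "maxT_non_trend",
                      window = c("2003-12-01", "2004-02-29"))
#> Excess-risk regression: logRR ~ maxT_non_trend  (n = 91 )
#>                estimate std_error        t p_value
#> (Intercept)    -0.01613   0.01779 -0.90649 0.36712
#> maxT_non_trend  0.01999   0.01293  1.54649 0.12554
#> Adjusted R-squared: 0.0152
```

(This scenario couples temperature to mortality only through the 6-day
spike, so a summer-wide association is weak by design.)

A command-line front end with `decompose`, `significance`, `excess`,
`regress`, `simulate` and `compare-classical` subcommands is installed at
`system.file("cli", "hht", package = "hhtexcess")`.

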