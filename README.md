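# lumikin

Kinetic modelling and rhythm analysis of luciferase protein-fusion
reporters, for plant circadian biologists quantifying clock proteins with
plate-reader luminometry.

Firefly luciferase (FLUC) fusions report rhythmic gene expression well
precisely because FLUC activity is unstable in planta — but that same
instability makes a FLUC translational fusion a poor proxy for total
protein abundance. The stable NanoLUC enzyme is the natural complement,
and because the two enzymes use different substrates they can be tracked
in the same material. `lumikin` provides the quantitative framework for
interpreting such dual-reporter experiments:

* **Reporter model** — a pair of periodically forced linear ODEs for
  fusions of a clock protein (BOA) to NanoLUC and FLUC,

  $$\dot c = k_1 e^{\sin(2\pi t/25 + 10)} - \delta c, \qquad
    \delta = k_2 + k_3 \text{ (NL)} \;\text{or}\; k_2 + k_4 \text{ (FLUC)},$$

  with simulation (`simulate_reporters()`), periodic-steady-state
  analysis, joint fitting with identifiability diagnostics
  (`fit_reporter_model()`) and derived half-lives. A first-order filter
  passes the forcing rhythm with gain `delta / sqrt(delta^2 + omega^2)`,
  which is why the unstable FLUC fusion shows high-amplitude rhythms while
  the stable NanoLUC fusion gives a flatter, brighter trace.
* **Enzyme stability** — log-linear first-order decay fits
  (`fit_decay()`), half-life arithmetic, Q10 temperature scaling and
  correction of measurements made with an aged calibrator enzyme.
* **Calibration** — log-log calibration curves from serial dilutions
  (`fit_calibration()`), per-step linearity reports, matrix-inhibition
  ratios, and inversion to relative enzyme amounts (`infer_amount()`).
* **Rhythm analysis** — FFT-seeded cosine least squares
  (`estimate_rhythm()`), a single-component analogue of FFT-NLLS, giving
  period, phase, amplitude and relative amplitude per well.
* **Synthetic data** — generators for decay series, dilution ladders and
  multi-well plate experiments with Poisson counting noise plus
  multiplicative log-normal variation, so every estimator can be validated
  against known ground truth.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` figures, and a
`run_pipeline()` wrapper (plus a thin CLI in `inst/cli/lumikin.R`) for
reproducible end-to-end runs with a manifest.

## Worked example

Simulate a four-well experiment (two wells per reporter, 96 h, 30-min
sampling, 5% CV noise), estimate each well's rhythm, and re-fit the model:

```r
library(lumikin)

traces <- generate_plate_experiment(
  plate_design(n_nl = 2, n_fluc = 2), reporter_params(),
  duration_h = 96, noise = noise_model(multiplicative_cv = 0.05), seed = 1
)
estimate_rhythms(traces)
#> # A tibble: 4 × 13
#>   well  reporter genotype replicate period_h phase_rad amplitude mean_level
#>   <chr> <chr>    <chr>        <int>    <dbl>     <dbl>     <dbl>      <dbl>
#> 1 F01   FLUC     BOA-FLUC         1     25.0     1.29       165.       275.
#> 2 F02   FLUC     BOA-FLUC         2     25.0     1.29       170.       275.
#> 3 N01   NL       BOA-NL           1     25.1     0.931      173.       571.
#> 4 N02   NL       BOA-NL           2     25.1     0.958      179.       569.
#> # ℹ 5 more variables: linear_trend <dbl>, relative_amplitude <dbl>, ...
```

Both reporters oscillate at the 25 h forcing period; the FLUC wells have
relative amplitude ≈ 0.6 against ≈ 0.3 for the NanoLUC wells, whose mean
level is about twice as high — the signature of a stable reporter
integrating the same translation input.

```r
fit <- fit_reporter_model(traces,
                          params_init = reporter_params(k1 = 80, k2 = 0.12,
                                                        k4 = 0.25))
fit
#> <reporter_fit> channels: FLUC + NL, n = 772
#>   k1      50.314 (fitted)
#>   k2    0.080593 (fitted)
#>   k3      0.0121 (fixed)
#>   k4     0.15139 (fitted)
#>   a        0.004 (fixed)
#>   rss = 666082  converged = TRUE
derived_half_lives(fit$params)
#> # A tibble: 3 × 4
#>   species          rate_per_h half_life_h no_decay
#>   <chr>                 <dbl>       <dbl> <lgl>
#> 1 BOA protein          0.0806        8.60 FALSE
#> 2 NanoLUC activity     0.0121       57.3  FALSE
#> 3 FLUC activity        0.151         4.58 FALSE
```

The fit recovers the generating constants (`k1 = 50`, `k2 = 0.08`,
`k4 = 0.15`) to ~1% from twofold-perturbed starting values, and the
half-life table reads off the biology: the fusion partner (~8.7 h)
degrades much faster than NanoLUC activity decays (~57 h), so the NanoLUC
fusion tracks protein abundance, while FLUC activity (~4.6 h) dominates
its own reporter's dynamics.

For enzyme stability and calibration:

```r
series <- generate_decay_series(rate_from_half_life(37.2 * 24),
                                times_h = seq(0, 28 * 24, by = 24),
                                noise = noise_model(multiplicative_cv = 0.02,
                                                    counting = FALSE),
                                seed = 1)
fit_decay(series)
#> <decay_fit> (log-linear OLS)
#>   rate: 0.0007892 1/h  half-life: 878.3 h (36.6 days)
#>   r-squared: 0.9869  rate std. error: 1.75e-05 1/h  n = 29
```

A 37-day half-life means the calibrator keeps >95% activity over 2 days
and >80% over a week at 4 °C; `infer_amount()` can compensate exactly for
older calibrators via `calibrator_age_h`.

See `vignettes/reporter-kinetics.Rmd` for the model's assumptions,
numerical choices and limitations.

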