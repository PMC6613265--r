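# Demonstration pipeline configuration: synthetic plate experiment with the
# default reporter-model constants, a stability series, a calibration
# ladder, and per-well rhythm analysis.
seed: 42
stages:
  - generate
  - decay
  - calibration
  - rhythm
model:
  k1: 50
  k2: 0.08
  k3: 0.0121
  k4: 0.15
  a: 0.004
  period_h: 25
  phase_rad: 10
noise:
  multiplicative_cv: 0.05
  counting_integration_s: 1.5
  baseline_cps: 0
  counting: true
generate:
  duration_h: 96
  sampling_interval_h: 0.5
  n_nl: 2
  n_fluc: 2
decay:
  half_life_days: 37.2
  duration_days: 28
  interval_h: 24
  a0: 100000
calibration:
  top_concentration: 0.1
  fold: 10
  n_steps: 6
  response_slope: 1
  signal_at_top: 1000000
rhythm:
  period_min_h: 15
  period_max_h: 35
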