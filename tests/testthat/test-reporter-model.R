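test_that("the forcing evaluates to its closed form and is periodic", {
  p <- reporter_params()
  expect_equal(forcing(0, p), 50 * exp(sin(10)))
  expect_equal(forcing(0, p), 29.02, tolerance = 1e-4)
  # at the forcing maximum sin(.) = 1: value k1 * e
  t_max <- 25 * (pi / 2 - 10 + 4 * pi) / (2 * pi)
  expect_equal(forcing(t_max, p), 50 * exp(1))
  expect_equal(forcing(t_max, p), 135.91, tolerance = 1e-4)
  t <- seq(0, 50, 0.7)
  expect_equal(forcing(t, p), forcing(t + 25, p))
  expect_true(all(forcing(t, p) > 0))
})

test_that("with no forcing the states decay homogeneously", {
  p <- reporter_params(k1 = 0)
  t <- seq(0, 30, 0.5)
  sim <- simulate_reporters(p, t, init = c(NL = 100, FLUC = 80))
  expect_equal(sim$cBNL, 100 * exp(-(p$k2 + p$k3) * t), tolerance = 1e-7)
  expect_equal(sim$cBFLUC, 80 * exp(-(p$k2 + p$k4) * t), tolerance = 1e-7)
})

test_that("constant forcing drives the state to F0/delta", {
  p <- reporter_params()
  F0 <- p$k1 * besselI(1, 0)  # the sinusoid's mean, switched constant
  sim <- simulate_reporters(p, seq(0, 400, 1), init = "zero",
                            forcing_fn = function(s) rep(F0, length(s)))
  expect_equal(tail(sim$cBFLUC, 1), F0 / (p$k2 + p$k4), tolerance = 1e-6)
  expect_equal(tail(sim$cBNL, 1), F0 / (p$k2 + p$k3), tolerance = 1e-4)
})

test_that("numerical integration matches the integrating-factor oracle", {
  p <- reporter_params()
  t <- seq(0, 100, 2.5)
  sim <- simulate_reporters(p, t, init = "zero")
  oracle_nl <- quadrature_state(t, p$k2 + p$k3, p)
  oracle_fl <- quadrature_state(t, p$k2 + p$k4, p)
  expect_lt(max(abs(sim$cBNL[-1] - oracle_nl[-1]) / oracle_nl[-1]), 1e-6)
  expect_lt(max(abs(sim$cBFLUC[-1] - oracle_fl[-1]) / oracle_fl[-1]), 1e-6)
})

test_that("the model is linear in k1 and collapses when k3 equals k4", {
  t <- seq(0, 60, 0.5)
  a <- simulate_reporters(reporter_params(k1 = 50), t, init = "zero")
  b <- simulate_reporters(reporter_params(k1 = 100), t, init = "zero")
  expect_equal(b$cBNL, 2 * a$cBNL, tolerance = 1e-8)
  same <- simulate_reporters(reporter_params(k3 = 0.1, k4 = 0.1), t)
  expect_equal(same$cBNL, same$cBFLUC, tolerance = 1e-8)
})

test_that("FLUC period-average matches k1 I0(1) / (k2 + k4)", {
  p <- reporter_params()
  sim <- simulate_reporters(p, seq(0, 25, 0.05))
  expect_equal(period_mean(sim$cBFLUC), 50 * besselI(1, 0) / 0.23,
               tolerance = 1e-4)
})

test_that("periodic steady state repeats and has the analytic mean and gain", {
  p <- reporter_params()
  for (rep_ch in c("NL", "FLUC")) {
    delta <- if (rep_ch == "NL") p$k2 + p$k3 else p$k2 + p$k4
    pss <- periodic_steady_state(p, rep_ch, dt = 0.05)
    expect_equal(pss$state[1], pss$state[nrow(pss)], tolerance = 1e-6)
    expect_equal(period_mean(pss$state), p$k1 * besselI(1, 0) / delta,
                 tolerance = 1e-5)
    # fundamental relative amplitude attenuated by delta/sqrt(delta^2+w^2)
    omega <- 2 * pi / p$period_h
    tt <- pss$time_h[-nrow(pss)]
    y <- pss$state[-nrow(pss)]
    f <- forcing(tt, p)
    ra_out <- Mod(fundamental_coef(tt, y, omega)) / mean(y)
    ra_in <- Mod(fundamental_coef(tt, f, omega)) / mean(f)
    expect_equal(ra_out / ra_in, harmonic_gain(delta, omega),
                 tolerance = 1e-3)
  }
  expect_equal(harmonic_gain(0.23, period_h = 25), 0.675, tolerance = 1e-3)
  expect_equal(harmonic_gain(0.0921, period_h = 25), 0.344, tolerance = 1e-3)
  expect_error(periodic_steady_state(reporter_params(k2 = 0, k3 = 0), "NL"),
               "attractor")
})

test_that("filter gain is monotone in the decay rate", {
  # faster-decaying reporters pass more of the rhythm
  deltas <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(harmonic_gain(deltas, period_h = 25)) > 0))
})

test_that("derived half-lives reproduce the model's printed values", {
  hl <- derived_half_lives(reporter_params())
  expect_equal(hl$half_life_h[hl$species == "BOA protein"], 8.66,
               tolerance = 1e-3)
  expect_equal(hl$half_life_h[hl$species == "NanoLUC activity"], 57.3,
               tolerance = 1e-3)
  expect_equal(hl$half_life_h[hl$species == "FLUC activity"], 4.62,
               tolerance = 1e-3)
  zero <- derived_half_lives(reporter_params(k4 = 0))
  expect_identical(hl$no_decay, rep(FALSE, 3))
  expect_true(zero$no_decay[zero$species == "FLUC activity"])
  expect_identical(zero$half_life_h[zero$species == "FLUC activity"], Inf)
})

test_that("the published parameter table loads with a logged discrepancy", {
  expect_message(p <- reporter_params_published(), "half-life")
  expect_equal(p$k2, 0.8)
})

test_that("noiseless joint fit recovers k1, k2, k4 from doubled guesses", {
  truth <- reporter_params()
  traces <- generate_plate_experiment(plate_design(1, 1), truth,
                                      duration_h = 72)
  guess <- reporter_params(k1 = 100, k2 = 0.16, k4 = 0.30)
  fit <- fit_reporter_model(traces, params_init = guess)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(fit$params$k1, truth$k1, tolerance = 0.01)
  expect_equal(fit$params$k2, truth$k2, tolerance = 0.01)
  expect_equal(fit$params$k4, truth$k4, tolerance = 0.01)
  expect_equal(fit$params$k3, truth$k3)  # held fixed
})

test_that("structurally unidentifiable masks are flagged", {
  traces <- generate_plate_experiment(plate_design(0, 1), duration_h = 60)
  expect_warning(
    fit <- fit_reporter_model(traces, free = c("k1", "k2", "k4")),
    "Degenerate"
  )
  expect_true(fit$degenerate)
  # only the sum k2 + k4 is pinned down on a single channel
  expect_equal(fit$params$k2 + fit$params$k4, 0.23, tolerance = 0.01)
  both <- generate_plate_experiment(plate_design(1, 1), duration_h = 60)
  expect_warning(
    fit2 <- fit_reporter_model(both, free = c("k1", "k2", "k3", "k4")),
    "Degenerate"
  )
  expect_true(fit2$degenerate)
})

test_that("simulation and fitting reject malformed inputs", {
  p <- reporter_params()
  expect_error(simulate_reporters(p, c(0, 2, 1)), "increasing")
  expect_error(simulate_reporters(p, 0:10, init = c(NL = -1, FLUC = 0)),
               "non-negative")
  bad <- generate_plate_experiment(plate_design(1, 1), duration_h = 60)
  bad$signal_cps[3] <- NaN
  expect_error(fit_reporter_model(bad), "non-finite")
  expect_error(
    fit_reporter_model(generate_plate_experiment(plate_design(1, 1),
                                                 duration_h = 60),
                       free = "k9"),
    "Unknown free parameter"
  )
  expect_error(reporter_params(k2 = -1), "non-negative")
})
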