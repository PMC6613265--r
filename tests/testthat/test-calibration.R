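test_that("an ideal ladder fits with slope 1 and r-squared 1", {
  curve <- fit_calibration(generate_dilution_series(fold = 10, n_steps = 6))
  expect_equal(curve$log10_slope, 1, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1, tolerance = 1e-10)
  expect_equal(curve$n_points_used, 6)
  expect_false(curve$low_n)
})

test_that("a two-point ladder is an exact line flagged low-n", {
  curve <- fit_calibration(generate_dilution_series(fold = 2, n_steps = 2))
  expect_true(curve$low_n)
  expect_equal(curve$r_squared, 1)
})

test_that("saturated points are excluded and the slope refits cleanly", {
  clipped <- generate_dilution_series(fold = 10, n_steps = 5,
                                      signal_at_top = 1e6,
                                      saturation_ceiling = 5e5)
  curve <- fit_calibration(clipped, saturation_ceiling = 5e5)
  expect_equal(curve$n_points_used, 4)
  expect_equal(curve$n_excluded, 1)
  # remaining points still carry the generating slope
  expect_equal(curve$log10_slope, 1, tolerance = 1e-10)
  expect_lt(curve$linear_range[2], 0.1)
  # nothing usable -> informative error
  expect_error(
    fit_calibration(generate_dilution_series(n_steps = 3),
                    saturation_ceiling = 0.1),
    "saturated"
  )
})

test_that("linearity report flags per-step departures from the nominal fold", {
  ideal <- linearity_report(generate_dilution_series(fold = 10, n_steps = 5))
  expect_equal(ideal$ratio, rep(10, 4))
  expect_equal(max(ideal$deviation), 0)
  sub <- linearity_report(generate_dilution_series(fold = 10, n_steps = 5,
                                                   response_slope = 0.9))
  expect_equal(sub$ratio, rep(10^0.9, 4))
  expect_equal(sub$deviation, rep((10 - 10^0.9) / 10, 4), tolerance = 1e-10)
  # a single 1.5x outlier perturbs exactly the two adjacent steps
  d <- generate_dilution_series(fold = 10, n_steps = 5)
  d$signal_cps[3] <- d$signal_cps[3] * 1.5
  rep_out <- linearity_report(d)
  expect_equal(sum(rep_out$deviation > 0.01), 2)
  expect_equal(rep_out$ratio[2], 10 / 1.5)
  expect_equal(rep_out$ratio[3], 15)
})

test_that("zero-signal steps are marked undefined, not fatal", {
  d <- generate_dilution_series(fold = 10, n_steps = 4)
  d$signal_cps[3] <- 0
  rep_out <- linearity_report(d)
  expect_true(rep_out$undefined[2])
  expect_true(is.na(rep_out$ratio[2]))
  expect_false(any(rep_out$undefined[-2]))
})

test_that("matrix inhibition is the extract/buffer ratio at matched dilutions", {
  extract <- generate_dilution_series(matrix = "plant_extract")
  buffer <- generate_dilution_series(matrix = "buffer")
  same <- matrix_inhibition(dplyr::bind_rows(extract, buffer))
  expect_equal(same$ratio, rep(1, 6))
  extract$signal_cps <- extract$signal_cps * 0.9
  down <- matrix_inhibition(dplyr::bind_rows(extract, buffer))
  expect_equal(down$ratio, rep(0.9, 6))
  shifted <- generate_dilution_series(top_concentration = 0.05,
                                      matrix = "plant_extract")
  expect_error(matrix_inhibition(dplyr::bind_rows(shifted, buffer)),
               "matched")
})

test_that("generation-time inhibition of 0.85 is recovered by Monte Carlo", {
  noise <- noise_model(multiplicative_cv = 0.02, counting = FALSE)
  ratios <- vapply(1:100, function(s) {
    both <- dplyr::bind_rows(
      generate_dilution_series(matrix = "plant_extract", inhibition = 0.85,
                               noise = noise, seed = s),
      generate_dilution_series(matrix = "buffer", noise = noise,
                               seed = s + 10000)
    )
    mean(matrix_inhibition(both)$ratio)
  }, numeric(1))
  expect_gt(mean(ratios), 0.83)
  expect_lt(mean(ratios), 0.87)
})

test_that("inference inverts the curve and is monotone", {
  ladder <- generate_dilution_series(fold = 10, n_steps = 6)
  curve <- fit_calibration(ladder)
  # fit-then-infer returns each calibration point's concentration
  inferred <- infer_amount(ladder$signal_cps, curve)
  expect_equal(inferred$concentration, ladder$dilution_factor,
               tolerance = 1e-10)
  expect_false(any(inferred$extrapolated))
  # proportionality and monotonicity
  one <- infer_amount(1e3, curve)$concentration
  ten <- infer_amount(1e4, curve)$concentration
  expect_equal(ten / one, 10, tolerance = 1e-10)
  s <- sort(10^runif(20, 1, 5))
  expect_true(all(diff(infer_amount(s, curve)$concentration) > 0))
  expect_error(infer_amount(-1, curve), "positive")
  expect_true(infer_amount(curve$signal_range[2] * 10, curve)$extrapolated)
})

test_that("an aged calibrator halves inferences after one half-life", {
  curve <- fit_calibration(generate_dilution_series())
  k <- rate_from_half_life(892.8)
  fresh <- infer_amount(5e4, curve)$concentration
  aged <- infer_amount(5e4, curve, calibrator_age_h = 892.8,
                       calibrator_decay_rate = k)$concentration
  expect_equal(aged / fresh, 0.5)
})

test_that("end-to-end aged-calibrator correction recovers the true amount", {
  # a calibrator that sat one half-life before the ladder was measured:
  # every calibration signal is halved relative to nominal concentration
  k <- rate_from_half_life(892.8)
  age <- 892.8
  f <- fraction_remaining(k, age)
  aged_ladder <- generate_dilution_series(signal_at_top = 1e6 * f)
  curve <- fit_calibration(aged_ladder)
  # a fresh unknown with true relative amount 0.01 in the fresh assay scale
  true_amount <- 0.01
  unknown_signal <- 1e6 * (true_amount / 0.1)
  raw <- infer_amount(unknown_signal, curve)$concentration
  corrected <- infer_amount(unknown_signal, curve, calibrator_age_h = age,
                            calibrator_decay_rate = k)$concentration
  expect_equal(raw, true_amount / f, tolerance = 1e-10)  # over-estimate
  expect_equal(corrected, true_amount, tolerance = 1e-10)
})
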