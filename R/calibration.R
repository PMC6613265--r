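#' Fit a log-log calibration curve to a serial-dilution series
#'
#' Ordinary least squares of `log10(signal)` on `log10(dilution_factor)`
#' (relative concentration). A slope of 1 means the assay response is
#' perfectly proportional to enzyme amount. Points at or above the
#' saturation ceiling, and points with non-positive signal, are excluded
#' before fitting; at least two usable points must remain.
#'
#' @param data A data frame with one row per dilution, e.g. from
#'   [generate_dilution_series()].
#' @param dilution_factor,signal Column names (tidy evaluation); defaults
#'   `dilution_factor` and `signal_cps`.
#' @param saturation_ceiling Detector ceiling in cps; points with
#'   `signal >= saturation_ceiling` are treated as saturated and dropped
#'   (default `Inf`: keep everything).
#'
#' @return An object of class `calibration_curve` with fields `log10_slope`,
#'   `log10_intercept`, `r_squared`, `linear_range` (dilution factors
#'   retained), `n_points_used`, `low_n` (exactly two usable points: the
#'   line is exact by construction), `signal_range`; has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' ladder <- generate_dilution_series(fold = 10, n_steps = 5)
#' fit_calibration(ladder)
#' @export
fit_calibration <- function(data, dilution_factor = dilution_factor,
                            signal = signal_cps, saturation_ceiling = Inf) {
  stopifnot(is.data.frame(data))
  d <- dplyr::pull(data, {{ dilution_factor }})
  s <- dplyr::pull(data, {{ signal }})
  if (any(d <= 0)) abort("Dilution factors must be positive.")
  saturated <- s >= saturation_ceiling
  usable <- !saturated & s > 0 & is.finite(s)
  if (sum(usable) < 2) {
    n_sat <- sum(saturated)
    n_zero <- sum(s <= 0)
    abort(sprintf(
      "Fewer than 2 usable calibration points (%d saturated, %d zero/negative of %d).",
      n_sat, n_zero, length(s)))
  }
  d_u <- d[usable]
  s_u <- s[usable]
  fit <- lm(log10(s_u) ~ log10(d_u))
  r2 <- suppressWarnings(summary(fit))$r.squared
  if (!is.finite(r2)) r2 <- 0
  structure(
    list(
      log10_slope = unname(coef(fit)[2]),
      log10_intercept = unname(coef(fit)[1]),
      r_squared = min(max(r2, 0), 1),
      linear_range = range(d_u),
      n_points_used = sum(usable),
      n_excluded = sum(!usable),
      low_n = sum(usable) == 2,
      signal_range = range(s_u),
      data = tibble::tibble(dilution_factor = d, signal_cps = s,
                            used = usable, saturated = saturated),
      model = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  log10(signal) = %.4f + %.4f * log10(concentration)\n",
              x$log10_intercept, x$log10_slope))
  cat(sprintf("  r-squared: %.4f  points used: %d (excluded: %d)%s\n",
              x$r_squared, x$n_points_used, x$n_excluded,
              if (x$low_n) "  [low-n: exact 2-point line]" else ""))
  cat(sprintf("  linear range: %.3g .. %.3g (relative concentration)\n",
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = c("log10_slope", "log10_intercept"),
    estimate = c(x$log10_slope, x$log10_intercept)
  )
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    log10_slope = x$log10_slope,
    log10_intercept = x$log10_intercept,
    r_squared = x$r_squared,
    n_points_used = x$n_points_used,
    n_excluded = x$n_excluded,
    low_n = x$low_n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$dilution_factor, .data$signal_cps,
                               shape = .data$used)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$log10_intercept,
                         slope = object$log10_slope, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Relative concentration (dilution factor)",
                  y = "Signal (cps)",
                  title = sprintf("Calibration curve: slope %.3f, r2 %.4f",
                                  object$log10_slope, object$r_squared),
                  shape = "Used in fit")
}

#' Per-step linearity report for a dilution ladder
#'
#' Computes the signal ratio of each consecutive pair of dilutions and its
#' relative deviation from the nominal fold change implied by the dilution
#' factors. An ideal 10-fold ladder has every ratio equal to 10 and zero
#' deviation. Steps whose denominator signal is zero are marked undefined
#' rather than raising an error.
#'
#' @inheritParams fit_calibration
#' @return A tibble with one row per step: `step`, `factor_from`,
#'   `factor_to`, `nominal_fold`, `ratio`, `deviation`
#'   (`abs(ratio - nominal_fold) / nominal_fold`), `undefined`.
#' @examples
#' linearity_report(generate_dilution_series(fold = 10, n_steps = 4))
#' @export
linearity_report <- function(data, dilution_factor = dilution_factor,
                             signal = signal_cps) {
  stopifnot(is.data.frame(data))
  d <- dplyr::pull(data, {{ dilution_factor }})
  s <- dplyr::pull(data, {{ signal }})
  if (length(d) < 2) abort("Need at least 2 points for a linearity report.")
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]
  s <- s[ord]
  n <- length(d)
  i <- seq_len(n - 1)
  ratio <- s[i] / s[i + 1]
  undefined <- s[i + 1] == 0
  ratio[undefined] <- NA_real_
  nominal <- d[i] / d[i + 1]
  tibble::tibble(
    step = i,
    factor_from = d[i],
    factor_to = d[i + 1],
    nominal_fold = nominal,
    ratio = ratio,
    deviation = abs(ratio - nominal) / nominal,
    undefined = undefined
  )
}

#' Matrix-inhibition ratio at matched dilutions
#'
#' Compares the signal of an enzyme diluted in a biological matrix (e.g.
#' plant extract) with its signal in clean buffer at the same dilution.
#' A ratio below 1 indicates inhibition by the matrix.
#'
#' @param data A data frame with columns `dilution_factor`, `signal_cps`
#'   and `matrix` containing both matrices (e.g. two
#'   [generate_dilution_series()] results bound together).
#' @param extract,buffer Matrix labels to compare.
#' @return A tibble with one row per matched dilution: `dilution_factor`,
#'   `extract_signal`, `buffer_signal`, `ratio`.
#' @examples
#' dplyr::bind_rows(
#'   generate_dilution_series(matrix = "plant_extract", inhibition = 0.85),
#'   generate_dilution_series(matrix = "buffer")
#' ) |> matrix_inhibition()
#' @export
matrix_inhibition <- function(data, extract = "plant_extract",
                              buffer = "buffer") {
  stopifnot(is.data.frame(data),
            all(c("dilution_factor", "signal_cps", "matrix") %in% names(data)))
  e <- data[data$matrix == extract, ]
  b <- data[data$matrix == buffer, ]
  matched <- dplyr::inner_join(
    dplyr::select(e, "dilution_factor", extract_signal = "signal_cps"),
    dplyr::select(b, "dilution_factor", buffer_signal = "signal_cps"),
    by = "dilution_factor"
  )
  if (nrow(matched) == 0) {
    abort("No matched dilution factor present in both matrices.")
  }
  dplyr::mutate(matched, ratio = .data$extract_signal / .data$buffer_signal)
}

#' Infer enzyme amount from a calibration curve
#'
#' Inverts the fitted log-log line,
#' `concentration = 10^((log10(signal) - intercept) / slope)`, then
#' compensates for calibrator aging: a calibrator that decayed for
#' `calibrator_age_h` before the curve was measured under-reports the
#' standard, so raw inversion over-estimates unknowns and the result is
#' scaled down by `fraction_remaining(rate, age)`.
#'
#' @param signal Positive measured signal(s) in cps.
#' @param curve A [fit_calibration()] result.
#' @param calibrator_age_h Age of the calibrator when the curve was
#'   measured, in hours.
#' @param calibrator_decay_rate First-order decay rate of the calibrator
#'   enzyme (1/h).
#' @return A tibble with columns `signal_cps`, `concentration` (relative,
#'   dilution-factor scale) and `extrapolated` (signal outside the fitted
#'   signal range).
#' @examples
#' curve <- fit_calibration(generate_dilution_series())
#' infer_amount(1e4, curve)
#' @export
infer_amount <- function(signal, curve, calibrator_age_h = 0,
                         calibrator_decay_rate = 0) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    abort("`signal` must be positive and finite.")
  }
  raw <- 10^((log10(signal) - curve$log10_intercept) / curve$log10_slope)
  corrected <- raw * fraction_remaining(calibrator_decay_rate, calibrator_age_h)
  tibble::tibble(
    signal_cps = signal,
    concentration = corrected,
    extrapolated = signal < curve$signal_range[1] | signal > curve$signal_range[2]
  )
}
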