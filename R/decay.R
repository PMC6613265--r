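#' Half-life from a first-order decay rate
#'
#' `half_life_from_rate()` returns `log(2) / rate`; `rate_from_half_life()`
#' is its inverse. For the reporter constants used here, a NanoLUC activity
#' decay of 0.0121 1/h corresponds to a half-life of about 57 h and the
#' firefly (FLUC) decay of 0.15 1/h to about 4.6 h.
#'
#' @param rate_per_h First-order rate in `1/h` (`> 0`).
#' @return Half-life in hours.
#' @examples
#' half_life_from_rate(0.0121)  # ~57 h
#' half_life_from_rate(0.15)    # ~4.6 h
#' @export
half_life_from_rate <- function(rate_per_h) {
  if (!is.numeric(rate_per_h) || any(is.na(rate_per_h)) || any(rate_per_h <= 0)) {
    abort("`rate_per_h` must be positive.")
  }
  log(2) / rate_per_h
}

#' @rdname half_life_from_rate
#' @param half_life_h Half-life in hours (`> 0`).
#' @export
rate_from_half_life <- function(half_life_h) {
  if (!is.numeric(half_life_h) || any(is.na(half_life_h)) || any(half_life_h <= 0)) {
    abort("`half_life_h` must be positive.")
  }
  log(2) / half_life_h
}

#' Fraction of activity remaining after first-order decay
#'
#' @param rate_per_h Decay rate in `1/h` (`>= 0`).
#' @param elapsed_h Elapsed time in hours (`>= 0`).
#' @return `exp(-rate_per_h * elapsed_h)`, in `(0, 1]`.
#' @examples
#' # a 37.2-day half-life retains >95% after 2 days and >80% after a week
#' k <- rate_from_half_life(37.2 * 24)
#' fraction_remaining(k, c(48, 168))
#' @export
fraction_remaining <- function(rate_per_h, elapsed_h) {
  if (any(rate_per_h < 0)) abort("`rate_per_h` must be non-negative.")
  if (any(elapsed_h < 0)) abort("`elapsed_h` must be non-negative.")
  exp(-rate_per_h * elapsed_h)
}

#' Scale a decay rate between temperatures with the Q10 rule
#'
#' Applies `rate * q10^((temp_to_c - temp_from_c) / 10)`, the standard Q10
#' temperature coefficient used to transfer an in vitro rate measured at one
#' temperature (e.g. enzyme storage at 4 degrees C) to assay conditions
#' (e.g. a plate reader at 21 degrees C).
#'
#' @param rate_per_h Rate in `1/h` (`>= 0`).
#' @param q10 Temperature coefficient (`> 0`), typically 2-3 for enzymatic
#'   processes; 2.5 is the conventional default here.
#' @param temp_from_c,temp_to_c Temperatures in Celsius.
#' @return The scaled rate in `1/h`.
#' @examples
#' q10_scale_rate(0.01, q10 = 2.5, temp_from_c = 4, temp_to_c = 21)
#' @export
q10_scale_rate <- function(rate_per_h, q10 = 2.5, temp_from_c, temp_to_c) {
  if (any(rate_per_h < 0)) abort("`rate_per_h` must be non-negative.")
  if (!is.numeric(q10) || any(q10 <= 0)) abort("`q10` must be positive.")
  rate_per_h * q10^((temp_to_c - temp_from_c) / 10)
}

#' Correct a measurement for calibrator aging
#'
#' A calibrator enzyme that has decayed before use emits less light per unit
#' of nominal concentration. Re-scaling a measured signal by the inverse of
#' the remaining fraction recovers the signal the fresh calibrator would
#' have produced.
#'
#' @param measured_signal Non-negative measured signal (cps).
#' @param calibrator_age_h Age of the calibrator in hours (`>= 0`).
#' @param rate_per_h Calibrator decay rate in `1/h` (`>= 0`).
#' @return `measured_signal / fraction_remaining(rate_per_h, calibrator_age_h)`;
#'   age 0 leaves the signal unchanged.
#' @export
decay_correct <- function(measured_signal, calibrator_age_h, rate_per_h) {
  if (any(measured_signal < 0)) abort("`measured_signal` must be non-negative.")
  measured_signal / fraction_remaining(rate_per_h, calibrator_age_h)
}

new_decay_fit <- function(rate_per_h, half_life_h, log_intercept, r_squared,
                          rate_std_err, no_decay, method, data, model = NULL) {
  structure(
    list(
      rate_per_h = rate_per_h,
      half_life_h = half_life_h,
      log_intercept = log_intercept,
      r_squared = r_squared,
      rate_std_err = rate_std_err,
      no_decay = no_decay,
      method = method,
      data = data,
      model = model
    ),
    class = "decay_fit"
  )
}

#' Fit a first-order decay model to an activity time course
#'
#' The canonical estimator is ordinary least squares of `log(activity)` on
#' time (log-linear fit): the decay rate is minus the slope and the
#' half-life is `log(2) / rate`. `fit_decay_nls()` fits the same model
#' `A0 * exp(-k t)` by nonlinear least squares on the raw scale, provided
#' for comparison; the log-linear fit is the default throughout the
#' package.
#'
#' If the fitted rate is not positive (the series does not decay), the
#' half-life is reported as `Inf` and the `no_decay` flag is set rather than
#' raising an error.
#'
#' @param data A data frame with one row per timepoint, e.g. from
#'   [generate_decay_series()].
#' @param time,activity Column names (tidy evaluation) holding time in hours
#'   and activity; defaults `time_h`, `activity`. All activities must be
#'   strictly positive for the log fit.
#'
#' @return An object of class `decay_fit` with fields `rate_per_h`,
#'   `half_life_h`, `log_intercept`, `r_squared`, `rate_std_err`,
#'   `no_decay`, plus [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' series <- generate_decay_series(rate_from_half_life(37.2 * 24),
#'                                 times_h = seq(0, 28 * 24, by = 24))
#' fit <- fit_decay(series)
#' fit$half_life_h / 24  # days
#' @export
fit_decay <- function(data, time = time_h, activity = activity) {
  stopifnot(is.data.frame(data))
  t <- dplyr::pull(data, {{ time }})
  a <- dplyr::pull(data, {{ activity }})
  if (length(t) < 2 || length(unique(t)) < 2) {
    abort("Need at least 2 distinct timepoints to fit a decay.")
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    abort("All activities must be positive and finite: log(activity) is undefined otherwise.")
  }
  fit <- lm(log(a) ~ t)
  s <- suppressWarnings(summary(fit))  # "essentially perfect fit" on noiseless data
  slope <- unname(coef(fit)[2])
  rate <- -slope
  # slopes below numerical noise (1e-12 1/h ~ half-life of 8e7 years) count
  # as no decay
  no_decay <- rate <= 1e-12
  # r.squared degenerates (NaN) for a constant series; report 0 there
  r2 <- s$r.squared
  if (!is.finite(r2)) r2 <- 0
  new_decay_fit(
    rate_per_h = rate,
    half_life_h = if (no_decay) Inf else log(2) / rate,
    log_intercept = unname(coef(fit)[1]),
    r_squared = min(max(r2, 0), 1),
    rate_std_err = unname(s$coefficients[2, "Std. Error"]),
    no_decay = no_decay,
    method = "log-linear OLS",
    data = tibble::tibble(time_h = t, activity = a),
    model = fit
  )
}

#' @rdname fit_decay
#' @export
fit_decay_nls <- function(data, time = time_h, activity = activity) {
  stopifnot(is.data.frame(data))
  t <- dplyr::pull(data, {{ time }})
  a <- dplyr::pull(data, {{ activity }})
  if (length(t) < 2) abort("Need at least 2 timepoints.")
  if (any(!is.finite(a)) || any(a <= 0)) abort("All activities must be positive and finite.")
  start_fit <- lm(log(a) ~ t)
  fit <- minpack.lm::nlsLM(
    a ~ A0 * exp(-k * t),
    start = list(A0 = exp(unname(coef(start_fit)[1])),
                 k = max(-unname(coef(start_fit)[2]), 1e-8)),
    lower = c(A0 = 0, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- summary(fit)$coefficients
  rate <- unname(est["k"])
  resid <- a - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((a - mean(a))^2)
  if (!is.finite(r2)) r2 <- 0
  no_decay <- rate <= 1e-12
  new_decay_fit(
    rate_per_h = rate,
    half_life_h = if (no_decay) Inf else log(2) / rate,
    log_intercept = log(unname(est["A0"])),
    r_squared = min(max(r2, 0), 1),
    rate_std_err = unname(se["k", "Std. Error"]),
    no_decay = no_decay,
    method = "nonlinear least squares",
    data = tibble::tibble(time_h = t, activity = a),
    model = fit
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> (", x$method, ")\n", sep = "")
  if (x$no_decay) {
    cat(sprintf("  rate: %.4g 1/h (no decay detected; half-life infinite)\n",
                x$rate_per_h))
  } else {
    cat(sprintf("  rate: %.4g 1/h  half-life: %.4g h (%.3g days)\n",
                x$rate_per_h, x$half_life_h, x$half_life_h / 24))
  }
  cat(sprintf("  r-squared: %.4f  rate std. error: %.3g 1/h  n = %d\n",
              x$r_squared, x$rate_std_err, nrow(x$data)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rate_per_h", "half_life_h", "log_intercept"),
    estimate = c(x$rate_per_h, x$half_life_h, x$log_intercept),
    std.error = c(x$rate_std_err, NA_real_, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    rate_per_h = x$rate_per_h,
    half_life_h = x$half_life_h,
    half_life_days = x$half_life_h / 24,
    r_squared = x$r_squared,
    rate_std_err = x$rate_std_err,
    no_decay = x$no_decay,
    n = nrow(x$data),
    method = x$method
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, ...) {
  pred <- tibble::tibble(
    time_h = seq(min(object$data$time_h), max(object$data$time_h), length.out = 200)
  )
  pred$activity <- exp(object$log_intercept - object$rate_per_h * pred$time_h)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$activity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time (h)", y = "Activity (cps)",
      title = sprintf("First-order decay: half-life %.3g h (%.3g days)",
                      object$half_life_h, object$half_life_h / 24)
    )
}
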