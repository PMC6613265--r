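#' Remove a baseline trend from a luminescence trace
#'
#' Standard pre-step of Fourier-seeded rhythm analysis: subtracts an
#' ordinary-least-squares line (mode `"linear"`), leaving a
#' zero-mean residual trace, or passes the trace through (mode `"none"`).
#'
#' @param data A data frame holding one well's trace.
#' @param mode `"linear"` or `"none"`.
#' @param time,signal Column names (tidy evaluation); defaults `time_h`,
#'   `signal_cps`.
#' @return The input data frame with the signal column replaced by the
#'   detrended signal.
#' @export
detrend_trace <- function(data, mode = c("linear", "none"),
                          time = time_h, signal = signal_cps) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data))
  if (mode == "none") return(tibble::as_tibble(data))
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ signal }})
  if (length(t) < 3) abort("Linear detrending needs at least 3 points.")
  resid <- unname(lm(y ~ t)$residuals)
  dplyr::mutate(tibble::as_tibble(data), {{ signal }} := resid)
}

wrap_phase <- function(phase_rad) {
  w <- phase_rad %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Circular difference between two phases
#'
#' @param phase1_rad,phase2_rad Phases in radians.
#' @return `phase1_rad - phase2_rad` wrapped to `(-pi, pi]`.
#' @examples
#' phase_difference(0.1, 2 * pi - 0.1)  # 0.2, not -6.08
#' @export
phase_difference <- function(phase1_rad, phase2_rad) {
  wrap_phase(phase1_rad - phase2_rad)
}

new_rhythm_fit <- function(period_h, phase_rad, amplitude, mean_level,
                           linear_trend, rss, converged, n, data,
                           diagnostics = NULL) {
  rel_amp <- if (is.na(mean_level) || mean_level == 0) NA_real_ else
    abs(amplitude) / abs(mean_level)
  structure(
    list(
      period_h = period_h,
      phase_rad = phase_rad,
      amplitude = amplitude,
      mean_level = mean_level,
      linear_trend = linear_trend,
      relative_amplitude = rel_amp,
      rss = rss,
      converged = converged,
      n = n,
      data = data,
      diagnostics = diagnostics
    ),
    class = "rhythm_fit"
  )
}

#' Estimate period, phase and amplitude of a luminescence trace
#'
#' A single-component analogue of the FFT-NLLS family of circadian period
#' estimators: the trace is linearly detrended, the discrete-Fourier peak
#' inside the period bounds seeds period, amplitude and phase, and a
#' nonlinear least-squares fit of
#' `mean + trend * t + amplitude * cos(2*pi*t/period + phase)`
#' refines all five parameters on the raw trace. One dominant circadian
#' component is assumed; no damping term is fitted.
#'
#' Sampling must be uniform (irregular grids are rejected, not resampled)
#' and the trace must span at least twice the lower period bound. If no
#' spectral peak falls within the bounds, a non-converged result carrying
#' the spectral diagnostics is returned instead of an error.
#'
#' @param data A data frame holding one well's trace.
#' @param period_bounds_h Numeric length-2: admissible period range in
#'   hours (default 15-35, bracketing circadian periods).
#' @param time,signal Column names (tidy evaluation); defaults `time_h`,
#'   `signal_cps`.
#' @return An object of class `rhythm_fit` with fields `period_h`,
#'   `phase_rad` (cosine phase at `t = 0`, wrapped to `(-pi, pi]`),
#'   `amplitude` (cps, `>= 0`), `mean_level` (cps, baseline at the trace
#'   midpoint), `linear_trend` (cps/h), `relative_amplitude`, `rss`,
#'   `converged`; has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' t <- seq(0, 96, 0.5)
#' trace <- tibble::tibble(time_h = t,
#'                         signal_cps = 100 + 20 * cos(2 * pi * t / 24))
#' estimate_rhythm(trace)
#' @export
estimate_rhythm <- function(data, period_bounds_h = c(15, 35),
                            time = time_h, signal = signal_cps) {
  stopifnot(is.data.frame(data), length(period_bounds_h) == 2,
            period_bounds_h[1] > 0, period_bounds_h[1] < period_bounds_h[2])
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ signal }})
  n <- length(t)
  if (n < 8) abort("Trace too short for rhythm estimation.")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    abort("Uniform sampling required; irregular time grids are rejected.")
  }
  dt <- dt[1]
  span <- t[n] - t[1]
  if (span < 2 * period_bounds_h[1]) {
    abort("Trace must span at least twice the lower period bound.")
  }

  base <- lm(y ~ t)
  mean0 <- unname(coef(base)[1])
  trend0 <- unname(coef(base)[2])
  resid <- unname(base$residuals)

  # candidate periods from the DFT grid (excluding DC)
  spec <- fft(resid)
  k <- seq_len(floor(n / 2))
  periods <- n * dt / k
  power <- Mod(spec[k + 1])^2
  in_bounds <- periods >= period_bounds_h[1] & periods <= period_bounds_h[2]
  diagnostics <- tibble::tibble(period_h = periods, power = power,
                                in_bounds = in_bounds)
  if (!any(in_bounds)) {
    return(new_rhythm_fit(
      period_h = NA_real_, phase_rad = NA_real_, amplitude = NA_real_,
      mean_level = mean0 + trend0 * mean(t), linear_trend = trend0,
      rss = sum(resid^2), converged = FALSE, n = n,
      data = tibble::tibble(time_h = t, signal_cps = y),
      diagnostics = diagnostics
    ))
  }
  k_best <- k[in_bounds][which.max(power[in_bounds])]
  period0 <- n * dt / k_best
  omega0 <- 2 * pi / period0
  coef0 <- (2 / n) * sum(resid * exp(-1i * omega0 * t))
  amp0 <- Mod(coef0)
  phase0 <- Arg(coef0)

  cosine_resid <- function(par) {
    par["m"] + par["b"] * t +
      par["A"] * cos(2 * pi * t / par["P"] + par["phi"]) - y
  }
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = c(m = mean0, b = trend0, A = amp0, P = period0, phi = phase0),
      fn = cosine_resid,
      lower = c(m = -Inf, b = -Inf, A = 0, P = period_bounds_h[1],
                phi = -2 * pi),
      upper = c(m = Inf, b = Inf, A = Inf, P = period_bounds_h[2],
                phi = 2 * pi),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )

  if (is.null(res) || !(res$info %in% 1:4)) {
    # fall back on the spectral seed, flagged non-converged
    return(new_rhythm_fit(
      period_h = period0, phase_rad = wrap_phase(phase0), amplitude = amp0,
      mean_level = mean0 + trend0 * mean(t), linear_trend = trend0,
      rss = sum((resid - amp0 * cos(omega0 * t + phase0))^2),
      converged = FALSE, n = n,
      data = tibble::tibble(time_h = t, signal_cps = y),
      diagnostics = diagnostics
    ))
  }
  est <- res$par
  amp <- unname(est["A"])
  phi <- unname(est["phi"])
  if (amp < 0) {  # canonical form: non-negative amplitude
    amp <- -amp
    phi <- phi + pi
  }
  new_rhythm_fit(
    period_h = unname(est["P"]),
    phase_rad = wrap_phase(phi),
    amplitude = amp,
    mean_level = unname(est["m"]) + unname(est["b"]) * mean(t),
    linear_trend = unname(est["b"]),
    rss = sum(res$fvec^2),
    converged = TRUE,
    n = n,
    data = tibble::tibble(time_h = t, signal_cps = y),
    diagnostics = diagnostics
  )
}

#' Estimate rhythms for every well of a plate experiment
#'
#' @param data Tidy traces (columns `well`, `time_h`, `signal_cps`, and any
#'   label columns, e.g. from [generate_plate_experiment()]).
#' @inheritParams estimate_rhythm
#' @return A tibble with one row per well: the well's label columns plus
#'   the [glance()] columns of its [estimate_rhythm()] fit.
#' @export
estimate_rhythms <- function(data, period_bounds_h = c(15, 35)) {
  stopifnot(is.data.frame(data),
            all(c("well", "time_h", "signal_cps") %in% names(data)))
  label_cols <- intersect(c("well", "reporter", "genotype", "replicate"),
                          names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(label_cols))) |>
    dplyr::group_modify(function(d, key) {
      glance(estimate_rhythm(d, period_bounds_h = period_bounds_h))
    }) |>
    dplyr::ungroup()
}

#' Relative amplitude of a fitted rhythm
#'
#' @param fit A [estimate_rhythm()] result.
#' @return `amplitude / mean_level`; errors if the mean level is zero.
#' @export
relative_amplitude <- function(fit) {
  stopifnot(inherits(fit, "rhythm_fit"))
  if (is.na(fit$mean_level) || fit$mean_level == 0) {
    abort("Relative amplitude is undefined for a zero mean level.")
  }
  abs(fit$amplitude) / abs(fit$mean_level)
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("<rhythm_fit>\n")
  if (is.na(x$period_h)) {
    cat("  no spectral peak within the period bounds (not converged)\n")
  } else {
    cat(sprintf("  period: %.3f h  phase: %.3f rad  amplitude: %.4g cps\n",
                x$period_h, x$phase_rad, x$amplitude))
    cat(sprintf("  mean level: %.4g cps  trend: %.3g cps/h  rel. amplitude: %.3f\n",
                x$mean_level, x$linear_trend, x$relative_amplitude))
    cat(sprintf("  rss: %.4g  converged: %s  n = %d\n", x$rss, x$converged, x$n))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rhythm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("period_h", "phase_rad", "amplitude", "mean_level",
             "linear_trend"),
    estimate = c(x$period_h, x$phase_rad, x$amplitude, x$mean_level,
                 x$linear_trend)
  )
}

#' @exportS3Method generics::glance
glance.rhythm_fit <- function(x, ...) {
  tibble::tibble(
    period_h = x$period_h,
    phase_rad = x$phase_rad,
    amplitude = x$amplitude,
    mean_level = x$mean_level,
    linear_trend = x$linear_trend,
    relative_amplitude = x$relative_amplitude,
    rss = x$rss,
    converged = x$converged,
    n = x$n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rhythm_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$time_h, .data$signal_cps)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "Time (h)", y = "Signal (cps)",
                  title = if (is.na(object$period_h)) {
                    "Rhythm fit (no peak in bounds)"
                  } else {
                    sprintf("Rhythm fit: period %.2f h, rel. amplitude %.3f",
                            object$period_h, object$relative_amplitude)
                  })
  if (!is.na(object$period_h)) {
    grid <- seq(min(object$data$time_h), max(object$data$time_h),
                length.out = 400)
    mid <- mean(object$data$time_h)
    pred <- tibble::tibble(
      time_h = grid,
      signal_cps = object$mean_level + object$linear_trend * (grid - mid) +
        object$amplitude * cos(2 * pi * grid / object$period_h +
                               object$phase_rad)
    )
    p <- p + ggplot2::geom_line(data = pred, colour = "steelblue")
  }
  p
}
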