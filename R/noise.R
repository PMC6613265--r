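#' Plate-reader noise model
#'
#' Describes the stochastic components applied to an ideal luminescence
#' signal, mimicking photon-counting luminometry: (1) shot noise from
#' Poisson photon counting over the integration window, (2) multiplicative
#' log-normal variation with a stated coefficient of variation (pipetting,
#' well position, seedling placement), and (3) an additive counts-per-second
#' background. Components are applied in that order, independently at each
#' timepoint.
#'
#' @param multiplicative_cv Coefficient of variation of the multiplicative
#'   log-normal component (dimensionless fraction, `>= 0`).
#' @param counting_integration_s Photon-counting integration time per well in
#'   seconds (`> 0`). The signal is treated as counts accumulated over this
#'   window, so the counting-noise variance of a signal `s` cps is
#'   `s / counting_integration_s`: halving the integration time doubles the
#'   variance contribution from counting.
#' @param baseline_cps Additive background in counts per second (`>= 0`).
#' @param counting Logical; apply Poisson counting noise? Set `FALSE` for a
#'   noise model with no shot-noise component.
#'
#' @return An object of class `noise_model`.
#' @seealso [noise_none()] for a fully deterministic model.
#' @examples
#' noise_model(multiplicative_cv = 0.05)
#' @export
noise_model <- function(multiplicative_cv = 0.05, counting_integration_s = 1.5,
                        baseline_cps = 0, counting = TRUE) {
  if (!is.numeric(multiplicative_cv) || length(multiplicative_cv) != 1 ||
      is.na(multiplicative_cv) || multiplicative_cv < 0) {
    abort("`multiplicative_cv` must be a single non-negative number.")
  }
  if (!is.numeric(counting_integration_s) || length(counting_integration_s) != 1 ||
      is.na(counting_integration_s) || counting_integration_s <= 0) {
    abort("`counting_integration_s` must be a single positive number.")
  }
  if (!is.numeric(baseline_cps) || length(baseline_cps) != 1 ||
      is.na(baseline_cps) || baseline_cps < 0) {
    abort("`baseline_cps` must be a single non-negative number.")
  }
  structure(
    list(
      multiplicative_cv = multiplicative_cv,
      counting_integration_s = counting_integration_s,
      baseline_cps = baseline_cps,
      counting = isTRUE(counting)
    ),
    class = "noise_model"
  )
}

#' Deterministic (noise-free) noise model
#'
#' @return A `noise_model` with no counting noise, zero multiplicative CV and
#'   zero baseline, so signals pass through unchanged.
#' @export
noise_none <- function() {
  noise_model(multiplicative_cv = 0, counting_integration_s = 1.5,
              baseline_cps = 0, counting = FALSE)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model>\n")
  cat("  counting:        ", if (x$counting) {
    sprintf("Poisson over %.3g s integration", x$counting_integration_s)
  } else "off", "\n", sep = "")
  cat(sprintf("  multiplicative:  CV = %.3g\n", x$multiplicative_cv))
  cat(sprintf("  baseline:        %.3g cps\n", x$baseline_cps))
  invisible(x)
}

#' Apply a noise model to an ideal signal
#'
#' Draws from the currently active RNG stream; callers that need
#' reproducibility should seed it (the generator functions do this via their
#' `seed` argument).
#'
#' @param signal_cps Numeric vector of ideal (noiseless) signals in cps.
#' @param noise A [noise_model()].
#' @return Numeric vector of perturbed signals, same length as `signal_cps`.
#' @export
apply_noise <- function(signal_cps, noise = noise_none()) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(signal_cps < 0, na.rm = TRUE)) {
    abort("`signal_cps` must be non-negative.")
  }
  out <- signal_cps
  if (noise$counting) {
    counts <- rpois(length(out), out * noise$counting_integration_s)
    out <- counts / noise$counting_integration_s
  }
  if (noise$multiplicative_cv > 0) {
    # log-normal with mean 1 and the requested CV
    sdlog <- sqrt(log1p(noise$multiplicative_cv^2))
    out <- out * rlnorm(length(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out + noise$baseline_cps
}

# Run `code` under a fixed seed when `seed` is given, without touching the
# caller's RNG state; otherwise use the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
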