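#' Generate a synthetic enzyme-stability decay series
#'
#' Emulates an in vitro stability experiment: an enzyme preparation stored at
#' a fixed temperature and re-assayed over time, its activity following
#' first-order decay `A(t) = A0 * exp(-rate * t)` perturbed by the noise
#' model.
#'
#' @param rate_per_h First-order decay rate in `1/h` (`>= 0`).
#' @param times_h Strictly increasing, non-negative sampling times in hours.
#' @param a0 Initial activity in cps (`> 0`).
#' @param noise A [noise_model()]; default noiseless.
#' @param seed Optional integer seed; identical arguments and seed reproduce
#'   identical output.
#' @param temperature_c Storage temperature in Celsius (metadata column).
#'
#' @return A tibble with columns `time_h`, `activity`, `temperature_c`.
#' @examples
#' # a ladder halving every hour
#' generate_decay_series(log(2), times_h = 0:2, a0 = 100)
#' @export
generate_decay_series <- function(rate_per_h, times_h, a0 = 1e5,
                                  noise = noise_none(), seed = NULL,
                                  temperature_c = 4) {
  if (!is.numeric(rate_per_h) || length(rate_per_h) != 1 || is.na(rate_per_h) ||
      rate_per_h < 0) {
    abort("`rate_per_h` must be a single non-negative number.")
  }
  if (length(times_h) == 0) abort("`times_h` must not be empty.")
  if (any(diff(times_h) <= 0)) abort("`times_h` must be strictly increasing.")
  if (!is.numeric(a0) || a0 <= 0) abort("`a0` must be positive.")
  ideal <- a0 * exp(-rate_per_h * times_h)
  activity <- with_seed_if(seed, apply_noise(ideal, noise))
  tibble::tibble(
    time_h = as.numeric(times_h),
    activity = activity,
    temperature_c = temperature_c
  )
}

#' Generate a synthetic serial-dilution ladder
#'
#' Emulates a calibration experiment in which a purified enzyme preparation
#' is serially diluted (e.g. 10-fold steps) in a buffer or plant-extract
#' matrix and each dilution assayed for luminescence. The ideal response is
#' `signal = signal_at_top * inhibition * (conc / top)^response_slope`, so
#' `response_slope = 1` is a perfectly proportional assay.
#'
#' @param top_concentration Relative concentration of the least-diluted point
#'   (`> 0`, `<= 1`; dilution factors are on this relative scale).
#' @param fold Fold dilution per step (`> 1`).
#' @param n_steps Number of points in the ladder (`>= 2`).
#' @param response_slope Log-log slope of the assay response; 1 = linear.
#' @param signal_at_top Ideal signal of the top point in cps.
#' @param matrix Matrix label, e.g. `"buffer"` or `"plant_extract"`.
#' @param inhibition Multiplicative activity factor applied by the matrix
#'   (1 = none; 0.85 means 15 percent inhibition).
#' @param saturation_ceiling Detector ceiling in cps; observed signals are
#'   clipped at this value (default `Inf`, no clipping).
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `dilution_factor` (strictly decreasing),
#'   `signal_cps`, `matrix`.
#' @examples
#' generate_dilution_series(fold = 10, n_steps = 4)
#' @export
generate_dilution_series <- function(top_concentration = 0.1, fold = 10,
                                     n_steps = 6, response_slope = 1,
                                     signal_at_top = 1e6, matrix = "buffer",
                                     inhibition = 1, saturation_ceiling = Inf,
                                     noise = noise_none(), seed = NULL) {
  if (!is.numeric(top_concentration) || top_concentration <= 0) {
    abort("`top_concentration` must be positive.")
  }
  if (fold <= 1) abort("`fold` must be > 1.")
  if (n_steps < 2) abort("`n_steps` must be >= 2.")
  conc <- top_concentration / fold^(seq_len(n_steps) - 1)
  ideal <- signal_at_top * inhibition * (conc / top_concentration)^response_slope
  signal <- with_seed_if(seed, apply_noise(ideal, noise))
  signal <- pmin(signal, saturation_ceiling)
  tibble::tibble(
    dilution_factor = conc,
    signal_cps = signal,
    matrix = matrix
  )
}

#' Describe the well layout of a reporter plate experiment
#'
#' @param n_nl,n_fluc Number of replicate wells carrying the NanoLUC (`NL`)
#'   and firefly (`FLUC`) fusion reporters.
#' @param genotype Named character vector giving the genotype label per
#'   reporter.
#'
#' @return A tibble with columns `well`, `reporter`, `genotype`, `replicate`.
#' @export
plate_design <- function(n_nl = 2, n_fluc = 2,
                         genotype = c(NL = "BOA-NL", FLUC = "BOA-FLUC")) {
  stopifnot(n_nl >= 0, n_fluc >= 0, n_nl + n_fluc > 0)
  design <- tibble::tibble(
    reporter = rep(c("NL", "FLUC"), times = c(n_nl, n_fluc)),
    replicate = c(seq_len(n_nl), seq_len(n_fluc))
  )
  design$genotype <- unname(genotype[design$reporter])
  design$well <- sprintf("%s%02d", substr(design$reporter, 1, 1), design$replicate)
  design[, c("well", "reporter", "genotype", "replicate")]
}

#' Generate a synthetic multi-well plate-reader experiment
#'
#' Simulates the reporter model for each well of a design and applies the
#' noise model independently per well, emulating an automated luminometer
#' reading a 96-well plate at a fixed interval. Replicate wells share the
#' same noiseless mean (the model-predicted observed signal for their
#' reporter) and differ only by noise.
#'
#' @param design A tibble as produced by [plate_design()] (columns `well`,
#'   `reporter`, `genotype`, `replicate`; `reporter` must be `"NL"` or
#'   `"FLUC"`).
#' @param params A [reporter_params()] object.
#' @param duration_h Total duration in hours; for rhythm analysis it should
#'   cover at least two forcing periods.
#' @param sampling_interval_h Sampling interval in hours (default 0.5, i.e.
#'   every 30 min).
#' @param noise A [noise_model()].
#' @param seed Optional integer seed (one shared RNG stream for the whole
#'   experiment).
#' @param init Initial condition passed to [simulate_reporters()].
#'
#' @return A tidy tibble with columns `well`, `time_h`, `signal_cps`,
#'   `reporter`, `genotype`, `replicate`.
#' @examples
#' exp <- generate_plate_experiment(plate_design(1, 1), duration_h = 50)
#' dplyr::count(exp, well)
#' @export
generate_plate_experiment <- function(design = plate_design(),
                                      params = reporter_params(),
                                      duration_h = 72,
                                      sampling_interval_h = 0.5,
                                      noise = noise_none(), seed = NULL,
                                      init = "steady_state") {
  stopifnot(is.data.frame(design))
  required <- c("well", "reporter", "genotype", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("`design` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(design$reporter), c("NL", "FLUC"))
  if (length(bad) > 0) {
    abort(paste0("Unknown reporter label(s): ", paste(bad, collapse = ", "),
                 " (expected \"NL\" or \"FLUC\")."))
  }
  if (sampling_interval_h <= 0) abort("`sampling_interval_h` must be positive.")
  times <- seq(0, duration_h, by = sampling_interval_h)
  sim <- simulate_reporters(params, times, init = init)
  mean_signal <- list(NL = sim$observed_NL, FLUC = sim$observed_FLUC)
  with_seed_if(seed, {
    purrr::pmap_dfr(design, function(well, reporter, genotype, replicate, ...) {
      tibble::tibble(
        well = well,
        time_h = times,
        signal_cps = apply_noise(mean_signal[[reporter]], noise),
        reporter = reporter,
        genotype = genotype,
        replicate = replicate
      )
    })
  })
}
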