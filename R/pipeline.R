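pipeline_stage_names <- c("generate", "decay", "calibration", "rhythm")

config_schema <- list(
  top = c("seed", "stages", "model", "noise", "generate", "decay",
          "calibration", "rhythm"),
  model = c("k1", "k2", "k3", "k4", "a", "a_fluc", "period_h", "phase_rad"),
  noise = c("multiplicative_cv", "counting_integration_s", "baseline_cps",
            "counting"),
  generate = c("duration_h", "sampling_interval_h", "n_nl", "n_fluc"),
  decay = c("half_life_days", "interval_h", "duration_days", "a0",
            "temperature_c"),
  calibration = c("top_concentration", "fold", "n_steps", "response_slope",
                  "signal_at_top"),
  rhythm = c("period_min_h", "period_max_h")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")))
  }
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with a mandatory integer `seed`, a `stages` list
#' (subset of `generate`, `decay`, `calibration`, `rhythm`), and optional
#' `model` (keys named after the model constants `k1`...`k4`, `a`),
#' `noise`, and per-stage parameter tables. Unknown keys anywhere are
#' rejected.
#'
#' @param config A file path to a YAML file, or an already-parsed list.
#' @return The validated configuration list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("No such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  check_keys(config, config_schema$top, "config")
  if (is.null(config$seed)) {
    abort("`seed` is mandatory: every stochastic stage must be seeded.")
  }
  if (!is.numeric(config$seed) || config$seed != round(config$seed)) {
    abort("`seed` must be an integer.")
  }
  config$stages <- config$stages %||% pipeline_stage_names
  bad <- setdiff(unlist(config$stages), pipeline_stage_names)
  if (length(bad) > 0) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  for (section in c("model", "noise", "generate", "decay", "calibration",
                    "rhythm")) {
    if (!is.null(config[[section]])) {
      check_keys(config[[section]], config_schema[[section]],
                 paste0("config$", section))
    }
  }
  config
}

write_fit_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — `generate` (synthetic plate
#' experiment to tidy CSV), `decay` (synthetic stability series plus
#' log-linear fit), `calibration` (synthetic dilution ladder plus log-log
#' curve), `rhythm` (per-well period estimates from the generated traces) —
#' and writes a plain-text manifest echoing the configuration, the seed,
#' the package version and an MD5 checksum per output file. Identical
#' configurations produce byte-identical outputs and manifests. If a stage
#' fails, its partial outputs are deleted and the error names the stage.
#'
#' @param config A config list or YAML path; see [read_run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a tibble manifest of the written files.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  params <- do.call(reporter_params, config$model %||% list())
  noise <- do.call(noise_model, config$noise %||% list())
  stages <- unlist(config$stages)

  files <- character(0)
  converged <- list()
  traces <- NULL

  run_stage <- function(stage, fn) {
    written <- character(0)
    note <- function(p) { written <<- c(written, p); p }
    tryCatch(fn(note), error = function(e) {
      unlink(written)
      abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)))
    })
    files <<- c(files, written)
  }

  if ("generate" %in% stages) {
    run_stage("generate", function(note) {
      g <- config$generate %||% list()
      design <- plate_design(n_nl = g$n_nl %||% 2, n_fluc = g$n_fluc %||% 2)
      traces <<- generate_plate_experiment(
        design, params,
        duration_h = g$duration_h %||% 72,
        sampling_interval_h = g$sampling_interval_h %||% 0.5,
        noise = noise, seed = seed
      )
      write_traces(traces, note(file.path(out_dir, "traces.csv")))
    })
  }

  if ("decay" %in% stages) {
    run_stage("decay", function(note) {
      d <- config$decay %||% list()
      hl_days <- d$half_life_days %||% 37.2
      series <- generate_decay_series(
        rate_per_h = rate_from_half_life(hl_days * 24),
        times_h = seq(0, (d$duration_days %||% 28) * 24,
                      by = d$interval_h %||% 24),
        a0 = d$a0 %||% 1e5,
        noise = noise, seed = seed + 1L,
        temperature_c = d$temperature_c %||% 4
      )
      readr::write_csv(series, note(file.path(out_dir, "decay_series.csv")),
                       progress = FALSE)
      fit <- fit_decay(series)
      converged$decay <<- !fit$no_decay
      write_fit_json(as.list(glance(fit)),
                     note(file.path(out_dir, "decay_fit.json")))
    })
  }

  if ("calibration" %in% stages) {
    run_stage("calibration", function(note) {
      cc <- config$calibration %||% list()
      ladder <- generate_dilution_series(
        top_concentration = cc$top_concentration %||% 0.1,
        fold = cc$fold %||% 10,
        n_steps = cc$n_steps %||% 6,
        response_slope = cc$response_slope %||% 1,
        signal_at_top = cc$signal_at_top %||% 1e6,
        noise = noise, seed = seed + 2L
      )
      readr::write_csv(ladder,
                       note(file.path(out_dir, "calibration_series.csv")),
                       progress = FALSE)
      curve <- fit_calibration(ladder)
      converged$calibration <<- curve$n_points_used >= 2
      write_fit_json(as.list(glance(curve)),
                     note(file.path(out_dir, "calibration_fit.json")))
    })
  }

  if ("rhythm" %in% stages) {
    run_stage("rhythm", function(note) {
      if (is.null(traces)) {
        trace_path <- file.path(out_dir, "traces.csv")
        if (!file.exists(trace_path)) {
          abort("no traces available; run the `generate` stage first")
        }
        traces <<- read_traces(trace_path)
      }
      r <- config$rhythm %||% list()
      fits <- estimate_rhythms(
        traces,
        period_bounds_h = c(r$period_min_h %||% 15, r$period_max_h %||% 35)
      )
      converged$rhythm <<- all(fits$converged)
      readr::write_csv(fits, note(file.path(out_dir, "rhythm_fits.csv")),
                       progress = FALSE)
    })
  }

  manifest_path <- file.path(out_dir, "manifest.txt")
  sums <- tools::md5sum(files)
  lines <- c(
    "# lumikin pipeline manifest",
    paste0("package_version: ", as.character(utils::packageVersion("lumikin"))),
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ", ")),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(config), "\n")[[1]]),
    "converged:",
    if (length(converged) > 0) {
      paste0("  ", names(converged), ": ", toupper(unlist(converged)))
    } else "  none",
    "checksums (md5):",
    paste0("  ", basename(files), "  ", unname(sums))
  )
  writeLines(lines, manifest_path)
  invisible(tibble::tibble(file = c(files, manifest_path),
                           md5 = c(unname(sums), unname(tools::md5sum(manifest_path)))))
}
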