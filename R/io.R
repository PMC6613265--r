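trace_schema <- c("well", "time_h", "signal_cps", "reporter", "genotype",
                  "replicate")

#' Read and write tidy luminescence traces
#'
#' The on-disk format is a plain UTF-8 CSV with one header row, '.' decimal
#' separator, and columns `well`, `time_h`, `signal_cps`, `reporter`,
#' `genotype`, `replicate`. `read_traces()` validates the schema (missing
#' columns and non-numeric time/signal values are reported with row
#' numbers) and canonicalises row order by `(well, time_h)`;
#' `write_traces()` writes doubles with full round-trip precision, so
#' `read_traces(write_traces(x, f))` reproduces `x` exactly.
#'
#' @param path File path.
#' @return `read_traces()`: a tibble in the schema above, sorted by
#'   `(well, time_h)`. `write_traces()`: the input, invisibly.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(trace_schema, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Trace file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column `%s` at data row %s.",
                    col, paste(head(bad, 5), collapse = ", ")))
    }
    if (anyNA(v)) {
      abort(sprintf("Missing value in column `%s` at data row %s.",
                    col, paste(head(which(is.na(v)), 5), collapse = ", ")))
    }
    v
  }
  out <- tibble::tibble(
    well = raw$well,
    time_h = parse_num(raw$time_h, "time_h"),
    signal_cps = parse_num(raw$signal_cps, "signal_cps"),
    reporter = raw$reporter,
    genotype = raw$genotype,
    replicate = parse_num(raw$replicate, "replicate")
  )
  dplyr::arrange(out, .data$well, .data$time_h)
}

#' @rdname read_traces
#' @param traces A data frame in the trace schema.
#' @export
write_traces <- function(traces, path) {
  stopifnot(is.data.frame(traces))
  missing_cols <- setdiff(trace_schema, names(traces))
  if (length(missing_cols) > 0) {
    abort(paste0("`traces` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(traces[, trace_schema], path, progress = FALSE)
  invisible(traces)
}
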