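#' Oxygen-trace tibbles
#'
#' An `o2_trace` is a tibble with columns `time_s` (seconds since the fish
#' was sealed in, strictly increasing), `o2_mgL` (dissolved oxygen, mg L^-1,
#' non-negative), `o2_percent_sat` (percent air saturation) and `phase`
#' (`"measure"`, `"flush"` or `"unknown"`), carrying the chamber and trial
#' metadata as attributes.
#'
#' @param data Tibble with at least `time_s` and `o2_mgL`.
#' @param chamber A [chamber_spec()].
#' @param fish_id,testing,trial_type Trial metadata (may be `NA`).
#' @return An `o2_trace` tibble.
#' @keywords internal
#' @export
new_o2_trace <- function(data, chamber, fish_id = NA_character_,
                         testing = NA_character_, trial_type = "fish") {
  if (!"o2_percent_sat" %in% names(data)) {
    data$o2_percent_sat <- 100 * data$o2_mgL / chamber$o2_full_saturation
  }
  if (!"phase" %in% names(data)) data$phase <- "unknown"
  validate_trace(data, chamber)
  structure(
    tibble::as_tibble(data[c("time_s", "o2_mgL", "o2_percent_sat", "phase")]),
    chamber = chamber,
    fish_id = fish_id,
    testing = testing,
    trial_type = trial_type,
    class = c("o2_trace", class(tibble::tibble()))
  )
}

validate_trace <- function(data, chamber) {
  if (nrow(data) == 0) {
    abort_shoalmet("trace has no samples.", "shoalmet_empty_trace")
  }
  dtime <- diff(data$time_s)
  if (any(dtime <= 0)) {
    row <- which(dtime <= 0)[1] + 1L
    abort_shoalmet(
      sprintf("time must be strictly increasing; first violation at row %d (t = %g s).",
              row, data$time_s[row]),
      "shoalmet_invalid_trace"
    )
  }
  if (any(data$o2_mgL < 0, na.rm = TRUE)) {
    abort_shoalmet("negative oxygen concentration in trace.",
                   "shoalmet_invalid_trace")
  }
  gaps <- which(dtime > 2 * chamber$sample_interval)
  if (length(gaps) > 0) {
    warning(sprintf("%d sampling gap(s) longer than twice the sample interval.",
                    length(gaps)), call. = FALSE)
  }
  invisible(data)
}

#' Chamber and trial metadata of a trace
#'
#' @param trace An `o2_trace`.
#' @return For `trace_chamber()`, the [chamber_spec()] the trace was recorded
#'   (or simulated) with.
#' @export
trace_chamber <- function(trace) attr(trace, "chamber")

#' Write an oxygen trace to CSV
#'
#' Canonical trace format: UTF-8 CSV with header `time_s, o2_mgL,
#' o2_percent_sat, phase`. Numbers are written at full (round-trip)
#' precision, so `read_trace(write_trace(x))` reproduces the samples exactly.
#'
#' @param trace An `o2_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' Read an oxygen trace from CSV
#'
#' Reads the canonical trace CSV (columns `time_s`, `o2_mgL` and/or
#' `o2_percent_sat`, optional `phase`). If only percent saturation is
#' present, concentrations are derived through the chamber's
#' `o2_full_saturation`; the reverse conversion fills in missing saturation.
#' Rows must be in strictly increasing time order.
#'
#' @param path CSV file.
#' @param chamber A [chamber_spec()] giving the oxygen solubility and cycle
#'   timing for this trial.
#' @param units Which column carries the oxygen signal: `"mgL"` (default) or
#'   `"percent_sat"`.
#' @return An `o2_trace`.
#' @export
read_trace <- function(path, chamber, units = c("mgL", "percent_sat")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort_shoalmet(sprintf("no such trace file: %s", path), "shoalmet_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("time_s", if (units == "mgL") "o2_mgL" else "o2_percent_sat")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort_shoalmet(
      sprintf("trace file %s lacks required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "shoalmet_format_error"
    )
  }
  if (nrow(data) == 0) {
    abort_shoalmet(sprintf("trace file %s has no data rows.", path),
                   "shoalmet_empty_trace")
  }
  if (units == "percent_sat" || !"o2_mgL" %in% names(data)) {
    data$o2_mgL <- data$o2_percent_sat / 100 * chamber$o2_full_saturation
  }
  if (!"o2_percent_sat" %in% names(data)) {
    data$o2_percent_sat <- 100 * data$o2_mgL / chamber$o2_full_saturation
  }
  new_o2_trace(data, chamber)
}

#' Read a Fire-Sting-style optode export
#'
#' Thin adapter for fibre-optic oxygen meter exports: a header block of
#' `#`-prefixed metadata lines followed by tab-separated columns whose first
#' two fields are time (s) and dissolved oxygen. The result is mapped onto
#' the canonical trace representation with phases `"unknown"` (annotate with
#' [annotate_phases()]).
#'
#' @inheritParams read_trace
#' @return An `o2_trace`.
#' @export
read_firesting_trace <- function(path, chamber, units = c("mgL", "percent_sat")) {
  units <- match.arg(units)
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 2) {
    abort_shoalmet("no data rows in Fire-Sting export.", "shoalmet_format_error")
  }
  data <- readr::read_tsv(I(body), show_col_types = FALSE, progress = FALSE)
  if (ncol(data) < 2) {
    abort_shoalmet("Fire-Sting export needs at least time and oxygen columns.",
                   "shoalmet_format_error")
  }
  out <- tibble::tibble(time_s = as.numeric(data[[1]]),
                        value = as.numeric(data[[2]]))
  if (units == "percent_sat") {
    out$o2_mgL <- out$value / 100 * chamber$o2_full_saturation
  } else {
    out$o2_mgL <- out$value
  }
  out$value <- NULL
  new_o2_trace(out, chamber)
}

#' Annotate flush/measure phases by cycle position
#'
#' Labels every sample of a trace as `"measure"` or `"flush"` from its
#' position in the repeating (measure, flush) cycle. `t0_offset` is the cycle
#' time already elapsed at the first sample: 0 means the trace starts at the
#' top of a measurement phase; `measure_duration` means it starts at the top
#' of a flush. Intervals are half-open in seconds: a sample exactly on a
#' transition belongs to the later phase. Traces that already carry phase
#' labels are returned unchanged.
#'
#' @param trace An `o2_trace`.
#' @param chamber A [chamber_spec()]; defaults to the trace's own chamber.
#' @param t0_offset Cycle position of the first sample, seconds.
#' @return The annotated `o2_trace`.
#' @examples
#' cfg <- sim_config(trial_duration = 6, seed = 1)
#' tr <- simulate_trial(chamber_spec(), list(fish_id = "F1", mass_g = 1.84),
#'                      "solitary", cfg)$trace
#' tr$phase <- "unknown"
#' table(annotate_phases(tr)$phase)
#' @export
annotate_phases <- function(trace, chamber = trace_chamber(trace), t0_offset = 0) {
  if (!all(trace$phase == "unknown")) {
    return(trace)
  }
  cycle <- chamber$measure_duration + chamber$flush_duration
  pos <- (trace$time_s + t0_offset) %% cycle
  trace$phase <- ifelse(pos < chamber$measure_duration, "measure", "flush")
  if (max(trace$time_s) - min(trace$time_s) < cycle) {
    warning("trace shorter than one full cycle; no complete measurement period.",
            call. = FALSE)
  }
  trace
}

#' Read and write fish metadata tables
#'
#' The metadata CSV has columns `fish_id`, `mass_g`, `length_cm`, `holding`
#' and optionally `testing` and `week` (for repeated morphometrics).
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_fish_metadata <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("fish_id", "mass_g", "length_cm")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort_shoalmet(
      sprintf("metadata file lacks column(s): %s", paste(missing, collapse = ", ")),
      "shoalmet_format_error"
    )
  }
  if (any(data$mass_g <= 0 | data$length_cm <= 0, na.rm = TRUE)) {
    abort_shoalmet("masses and lengths must be positive.", "shoalmet_invalid_trace")
  }
  data
}
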