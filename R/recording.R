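#' Build an accelerometer recording
#'
#' An `accel_recording` is a tibble with a time column `t` (seconds since the
#' start of the bout, strictly increasing) and three acceleration columns in
#' units of G. The pipeline consumes exactly one axis — the configured
#' anteroposterior axis, by default `az` for a phone worn at the waist — and
#' carries the others along unused. Irregularly sampled input is resampled by
#' linear interpolation onto a uniform grid at the median observed rate, and
#' the applied rate is recorded.
#'
#' @param data Data frame with a time column and three axis columns.
#' @param time Name of the time column (seconds).
#' @param axes Named character vector mapping `ax`, `ay`, `az` to column names
#'   in `data`.
#' @param units Either `"G"` (no conversion) or `"ms2"` (divided by 9.80665).
#' @param anteroposterior Which canonical axis (`"ax"`, `"ay"`, `"az"`) is the
#'   anteroposterior axis.
#'
#' @return A tibble of class `accel_recording` with columns `t`, `ax`, `ay`,
#'   `az`, and attributes `sample_rate` (Hz), `anteroposterior`, and
#'   `resampled` (logical).
#' @export
#' @examples
#' d <- data.frame(t = seq(0, 1, by = 0.01), x = 0, y = 0, z = sin(seq(0, 1, by = 0.01)))
#' rec <- accel_recording(d, axes = c(ax = "x", ay = "y", az = "z"))
#' sample_rate(rec)
accel_recording <- function(data,
                            time = "t",
                            axes = c(ax = "ax", ay = "ay", az = "az"),
                            units = c("G", "ms2"),
                            anteroposterior = "az") {
  units <- match.arg(units)
  stopifnot(is.data.frame(data))
  needed <- c(time, unname(axes))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fftgait_schema_error")
  }
  if (!anteroposterior %in% c("ax", "ay", "az")) {
    abort("`anteroposterior` must be one of 'ax', 'ay', 'az'",
          class = "fftgait_schema_error")
  }
  if (nrow(data) < 2) {
    abort("Empty input: need at least 2 samples", class = "fftgait_empty_error")
  }

  t <- as.numeric(data[[time]])
  vals <- lapply(axes[c("ax", "ay", "az")], function(cl) as.numeric(data[[cl]]))
  bad <- which(!is.finite(t) | !is.finite(vals[[1]]) |
                 !is.finite(vals[[2]]) | !is.finite(vals[[3]]))
  if (length(bad) > 0) {
    abort(paste0("Data error: non-finite value at row ", bad[1]),
          class = "fftgait_data_error")
  }
  if (any(diff(t) <= 0)) {
    abort("Timestamps must be strictly increasing",
          class = "fftgait_data_error")
  }
  if (units == "ms2") vals <- lapply(vals, function(v) v / STANDARD_GRAVITY)

  # 0-based time from bout start
  t <- t - t[1]
  dt <- diff(t)
  dt_med <- median(dt)
  fs <- 1 / dt_med
  resampled <- FALSE
  if (max(abs(dt - dt_med)) > 1e-6 * dt_med) {
    grid <- seq(0, t[length(t)], by = dt_med)
    vals <- lapply(vals, function(v) stats::approx(t, v, xout = grid)$y)
    t <- grid
    resampled <- TRUE
  }
  if (fs < 10 - 1e-9) {
    abort(sprintf("Sample rate %.2f Hz below the 10 Hz minimum", fs),
          class = "fftgait_data_error")
  }

  out <- tibble::tibble(t = t, ax = vals[[1]], ay = vals[[2]], az = vals[[3]])
  structure(out,
            class = c("accel_recording", class(out)),
            sample_rate = fs,
            anteroposterior = anteroposterior,
            resampled = resampled)
}

#' Read a recording from CSV
#'
#' @inheritParams accel_recording
#' @param path Path to a CSV file with a header row.
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path,
                           time = "t",
                           axes = c(ax = "ax", ay = "ay", az = "az"),
                           units = c("G", "ms2"),
                           anteroposterior = "az") {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fftgait_io_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  accel_recording(d, time = time, axes = axes, units = units,
                  anteroposterior = anteroposterior)
}

#' Write a recording to CSV
#'
#' @param rec An [accel_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  readr::write_csv(format_float_cols(tibble::as_tibble(rec)), path)
  invisible(path)
}

#' Sample rate of a recording in Hz
#' @param rec An [accel_recording()].
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate")

#' Anteroposterior signal of a recording
#' @param rec An [accel_recording()].
#' @return Numeric vector of the configured anteroposterior axis, in G.
#' @export
ap_signal <- function(rec) rec[[attr(rec, "anteroposterior") %||% "az"]]

#' Duration of a recording in seconds
#' @param rec An [accel_recording()].
#' @return Duration in seconds (span plus one sample period).
#' @export
recording_duration <- function(rec) {
  rec$t[nrow(rec)] - rec$t[1] + 1 / sample_rate(rec)
}

# all floats at 6 decimals in CSV output
format_float_cols <- function(d) {
  dplyr::mutate(d, dplyr::across(dplyr::where(is.double), ~ round(.x, 6)))
}

#' Write a per-window estimate table to CSV
#'
#' One row per window: start time, duration, active seconds, step frequency,
#' steps, step length, distance, velocity. Floats are written at 6 decimals
#' and round-trip losslessly through [read_window_table()].
#'
#' @param estimates Tibble of window estimates (see [estimate_windows()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(estimates, path) {
  if (nrow(estimates) == 0) {
    abort("No window estimates to write", class = "fftgait_empty_error")
  }
  cols <- c("window", "start", "duration", "active_s", "step_frequency",
            "steps", "step_length", "distance", "velocity")
  readr::write_csv(format_float_cols(estimates[, intersect(cols, names(estimates))]), path)
  invisible(path)
}

#' Read a per-window estimate table written by [write_window_table()]
#' @param path CSV path.
#' @return Tibble of window estimates.
#' @export
read_window_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fftgait_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a bout summary to CSV
#' @param summary One-row tibble from [summarize_bout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bout_summary <- function(summary, path) {
  if (nrow(summary) == 0) {
    abort("No summary to write", class = "fftgait_empty_error")
  }
  readr::write_csv(format_float_cols(summary), path)
  invisible(path)
}

#' Read a bout summary written by [write_bout_summary()]
#' @param path CSV path.
#' @return One-row tibble.
#' @export
read_bout_summary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fftgait_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Subject profile
#'
#' @param subject_id Opaque identifier.
#' @param height Standing height in meters (0.5 to 2.5).
#' @param dmd 1 for Duchenne muscular dystrophy, 0 for typically developing.
#' @return A one-row tibble with columns `subject_id`, `height`, `dmd`.
#' @export
subject_profile <- function(subject_id = "anon", height, dmd = 0) {
  stopifnot(is.numeric(height), length(height) == 1)
  if (height < 0.5 || height > 2.5) {
    abort("height must be between 0.5 and 2.5 m", class = "fftgait_domain_error")
  }
  if (!dmd %in% c(0, 1)) {
    abort("dmd must be 0 or 1", class = "fftgait_domain_error")
  }
  tibble::tibble(subject_id = subject_id, height = height, dmd = dmd)
}
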