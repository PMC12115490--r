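#' Per-window gait metrics from cadence and active time
#'
#' Applies the per-window formula chain: steps = step frequency x active
#' seconds; step length from the step-length model; distance = steps x step
#' length; velocity = distance / active seconds (0 when no second is
#' active). A step frequency of 0 forces steps, distance, and velocity to 0.
#' Fractional steps are retained per window.
#'
#' @param duration Window duration(s) in seconds (vectorized).
#' @param active_s Active seconds per window, in `[0, duration]`.
#' @param step_frequency Step frequency per window in Hz.
#' @param subject A [subject_profile()] row.
#' @param coefficients A [step_length_coefficients()] vector.
#' @return A tibble with columns `duration`, `active_s`, `step_frequency`,
#'   `steps`, `step_length`, `distance`, `velocity`.
#' @export
#' @examples
#' window_metrics(5, 4, 2.0, subject_profile(height = 1.30, dmd = 0))
window_metrics <- function(duration, active_s, step_frequency, subject,
                           coefficients = step_length_coefficients()) {
  if (any(active_s < 0) || any(active_s > ceiling(duration) + 1e-9)) {
    abort("active_s must lie in [0, duration]", class = "fftgait_domain_error")
  }
  sf <- step_frequency
  steps <- sf * active_s
  sl <- predict_step_length(sf, subject$height, subject$dmd, coefficients)
  distance <- steps * sl
  velocity <- ifelse(active_s > 0, distance / active_s, 0)
  tibble::tibble(duration = duration, active_s = active_s,
                 step_frequency = sf, steps = steps, step_length = sl,
                 distance = distance, velocity = velocity)
}

#' Estimate per-window gait parameters for a whole bout
#'
#' Runs the per-window stage of the pipeline on a preprocessed recording:
#' segmentation into 5 s windows, per-second activity classification against
#' the calibration threshold, FFT cadence selection, and the metric chain of
#' [window_metrics()].
#'
#' @param rec A preprocessed [accel_recording()].
#' @param threshold Activity threshold in G (from [calibrate()]).
#' @param subject A [subject_profile()] row.
#' @param config A [spectral_config()].
#' @param coefficients A [step_length_coefficients()] vector.
#' @param window_s Window length in seconds.
#' @return A tibble with one row per window: `window`, `start`, `partial`,
#'   plus the [window_metrics()] columns and `harmonic_rule` (whether the
#'   60%/60% rule replaced the dominant peak).
#' @export
estimate_windows <- function(rec, threshold, subject,
                             config = spectral_config(),
                             coefficients = step_length_coefficients(),
                             window_s = 5) {
  windows <- segment_windows(rec, window_s = window_s)
  fs <- attr(windows, "sample_rate")
  if (nrow(windows) == 0) {
    abort("Recording too short: no analysis windows", class = "fftgait_empty_error")
  }
  sel <- purrr::map_dfr(windows$samples, function(x) {
    select_step_frequency(window_spectrum(x, fs, config), config,
                          details = TRUE)
  })
  active <- purrr::map_int(windows$samples, function(x) {
    classify_active_seconds(x, fs, threshold)$active_s
  })
  m <- window_metrics(windows$duration, active, sel$step_frequency, subject,
                      coefficients)
  dplyr::bind_cols(windows[, c("window", "start", "partial")], m,
                   sel[, "harmonic_rule"])
}

#' Summarize a bout from its window estimates
#'
#' Totals are sums over windows; bout averages follow the published
#' conventions: average step frequency and average step velocity divide by
#' the TOTAL bout duration (active plus inactive time, reflecting
#' community-level mobility density), while average step length is total
#' distance over total steps. The 95th-percentile step velocity is taken
#' over per-window velocities of active windows (type-7 linear-interpolation
#' percentile) — a window-level approximation of the stride-velocity-95
#' endpoint, since this method carries no per-step timing.
#'
#' @param estimates A tibble from [estimate_windows()] (or any tibble with
#'   `duration`, `active_s`, `steps`, `distance`, `velocity`).
#' @param velocity_denominator `"total"` (published convention) or
#'   `"active"`: the time base for average step frequency and velocity.
#' @return A one-row tibble: `n_windows`, `total_duration`,
#'   `active_duration`, `total_steps`, `total_steps_rounded`,
#'   `avg_step_frequency`, `avg_step_length`, `avg_step_velocity`,
#'   `total_distance`, `p95_step_velocity`.
#' @export
summarize_bout <- function(estimates,
                           velocity_denominator = c("total", "active")) {
  velocity_denominator <- match.arg(velocity_denominator)
  if (nrow(estimates) == 0) {
    abort("No window estimates to summarize", class = "fftgait_empty_error")
  }
  total_duration <- sum(estimates$duration)
  active_duration <- sum(estimates$active_s)
  total_steps <- sum(estimates$steps)
  total_distance <- sum(estimates$distance)
  denom <- if (velocity_denominator == "total") total_duration else
    max(active_duration, .Machine$double.eps)
  act <- estimates$velocity[estimates$active_s > 0]
  tibble::tibble(
    n_windows = nrow(estimates),
    total_duration = total_duration,
    active_duration = active_duration,
    total_steps = total_steps,
    total_steps_rounded = round(total_steps),
    avg_step_frequency = total_steps / denom,
    avg_step_length = if (total_steps > 0) total_distance / total_steps else 0,
    avg_step_velocity = total_distance / denom,
    total_distance = total_distance,
    p95_step_velocity = if (length(act) > 0) {
      unname(quantile(act, 0.95, type = 7))
    } else 0)
}

#' Long-format timeline of a bout
#'
#' One row per window with the quantities of the activity-map display:
#' window start, step frequency, steps, step length, velocity, and
#' nondecreasing cumulative distance. Suitable for plotting with
#' [autoplot.gait_timeline()].
#'
#' @param estimates A tibble from [estimate_windows()].
#' @param path Optional CSV output path.
#' @return A tibble of class `gait_timeline`.
#' @export
export_timeline <- function(estimates, path = NULL) {
  if (nrow(estimates) == 0) {
    abort("No window estimates", class = "fftgait_empty_error")
  }
  out <- tibble::tibble(
    start = estimates$start,
    step_frequency = estimates$step_frequency,
    steps = estimates$steps,
    step_length = estimates$step_length,
    velocity = estimates$velocity,
    cumulative_distance = cumsum(estimates$distance))
  out <- structure(out, class = c("gait_timeline", class(out)))
  if (!is.null(path)) readr::write_csv(format_float_cols(out), path)
  out
}
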