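#' Pipeline configuration
#'
#' Collects every tunable constant of the estimation pipeline with the
#' published values as defaults: 5 s windows, a 0.3–4.6 Hz analysis band,
#' the 60%/60% harmonic rule, and the published step-length coefficients.
#'
#' @param window_s Analysis window length in seconds.
#' @param band_low,band_high Bandpass edges in Hz.
#' @param filter_order Butterworth prototype order.
#' @param spectral A [spectral_config()].
#' @param coefficients A [step_length_coefficients()] vector.
#' @param velocity_denominator `"total"` (published convention) or
#'   `"active"` for bout averages.
#' @param fallback_threshold Activity threshold in G used when no SC-L1
#'   recording or explicit threshold is supplied; applied with a loud
#'   warning, for exploratory runs only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 5,
                            band_low = 0.3, band_high = 4.6,
                            filter_order = 4,
                            spectral = spectral_config(band_low = band_low,
                                                       band_high = band_high),
                            coefficients = step_length_coefficients(),
                            velocity_denominator = c("total", "active"),
                            fallback_threshold = 0.05) {
  velocity_denominator <- match.arg(velocity_denominator)
  structure(list(window_s = window_s, band_low = band_low,
                 band_high = band_high, filter_order = filter_order,
                 spectral = spectral, coefficients = coefficients,
                 velocity_denominator = velocity_denominator,
                 fallback_threshold = fallback_threshold),
            class = "pipeline_config")
}

#' Run the full estimation pipeline on one bout
#'
#' calibrate -> preprocess -> per-window cadence and activity -> metrics ->
#' bout summary -> timeline. The activity threshold comes from the SC-L1
#' calibration recording when given, from `threshold` when supplied
#' directly, or — with a loud warning — from the configured fallback.
#' When a ground-truth object from [simulate_bout()] is supplied, the
#' bout-level percentage errors against truth are included.
#'
#' @param recording An [accel_recording()] of the bout.
#' @param subject A [subject_profile()] row.
#' @param scl1 Optional [accel_recording()] of the slow-walk calibration.
#' @param threshold Optional activity threshold in G (overrides `scl1`).
#' @param truth Optional `gait_truth` from [simulate_bout()].
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory: window table, summary, timeline,
#'   calibration profile, and a run manifest are written there as
#'   CSV/JSON.
#' @return A list of class `gait_pipeline_result`: `windows`, `summary`,
#'   `timeline`, `calibration` (profile or NULL), `threshold`, `errors`
#'   (tibble of per-metric percentage errors, or NULL), `manifest`.
#' @export
run_pipeline <- function(recording, subject, scl1 = NULL, threshold = NULL,
                         truth = NULL, config = pipeline_config(),
                         output_dir = NULL) {
  calibration <- NULL
  if (is.null(threshold)) {
    if (!is.null(scl1)) {
      calibration <- withCallingHandlers(
        calibrate(scl1, band_low = config$band_low,
                  band_high = config$band_high),
        error = function(e) {
          abort(paste0("Stage calibrate: ", conditionMessage(e)),
                class = "fftgait_stage_error", parent = e)
        })
      threshold <- calibration$threshold
    } else {
      warn(sprintf(
        "No SC-L1 recording or threshold supplied; using fallback threshold %.3f G (exploratory only)",
        config$fallback_threshold))
      threshold <- config$fallback_threshold
    }
  }

  pre <- tryCatch(
    preprocess_signal(recording, config$band_low, config$band_high,
                      config$filter_order),
    error = function(e) abort(paste0("Stage preprocess: ", conditionMessage(e)),
                              class = "fftgait_stage_error", parent = e))
  windows <- tryCatch(
    estimate_windows(pre, threshold, subject, config$spectral,
                     config$coefficients, config$window_s),
    error = function(e) abort(paste0("Stage estimate: ", conditionMessage(e)),
                              class = "fftgait_stage_error", parent = e))
  summary <- summarize_bout(windows, config$velocity_denominator)
  timeline <- export_timeline(windows)

  errors <- NULL
  if (!is.null(truth)) {
    pct <- function(est, ref) if (ref != 0) 100 * (est - ref) / ref else NA_real_
    errors <- tibble::tibble(
      metric = c("step_count", "step_frequency", "step_length",
                 "step_velocity", "distance"),
      reference = c(truth$total_steps, truth$avg_step_frequency,
                    truth$avg_step_length, truth$avg_step_velocity,
                    truth$total_distance),
      estimate = c(summary$total_steps, summary$avg_step_frequency,
                   summary$avg_step_length, summary$avg_step_velocity,
                   summary$total_distance))
    errors$pct_error <- mapply(pct, errors$estimate, errors$reference)
  }

  manifest <- list(
    window_s = config$window_s,
    band = c(config$band_low, config$band_high),
    filter_order = config$filter_order,
    spectral = unclass(config$spectral),
    coefficients = as.list(unclass(config$coefficients)),
    velocity_denominator = config$velocity_denominator,
    threshold = threshold,
    sample_rate = sample_rate(recording),
    subject = as.list(subject))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_window_table(windows, file.path(output_dir, "windows.csv"))
    write_bout_summary(summary, file.path(output_dir, "summary.csv"))
    export_timeline(windows, file.path(output_dir, "timeline.csv"))
    if (!is.null(calibration)) {
      write_calibration(calibration, file.path(output_dir, "calibration.json"))
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(windows = windows, summary = summary, timeline = timeline,
                 calibration = calibration, threshold = threshold,
                 errors = errors, manifest = manifest),
            class = "gait_pipeline_result")
}

#' @export
print.gait_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Gait pipeline result: %d windows over %.1f s (%.0f s active)\n",
    s$n_windows, s$total_duration, s$active_duration))
  cat(sprintf(
    "  steps %.1f, distance %.1f m, avg cadence %.2f Hz, avg velocity %.2f m/s\n",
    s$total_steps, s$total_distance, s$avg_step_frequency,
    s$avg_step_velocity))
  invisible(x)
}

#' Evaluate the pipeline against ground truth on a batch of bouts
#'
#' Runs [run_pipeline()] on each bout of a [simulate_validation_batch()]
#' (calibrating from each bout's own SC-L1) and collects per-bout reference
#' and estimated values of the five validated metrics.
#'
#' @param batch A tibble from [simulate_validation_batch()].
#' @param config A [pipeline_config()].
#' @return A tibble with one row per bout and metric: `bout_id`, `metric`,
#'   `reference`, `estimate`, `pct_error`.
#' @export
evaluate_batch <- function(batch, config = pipeline_config()) {
  purrr::map_dfr(seq_len(nrow(batch)), function(i) {
    res <- run_pipeline(batch$recording[[i]], batch$subject[[i]],
                        scl1 = batch$scl1[[i]], truth = batch$truth[[i]],
                        config = config)
    dplyr::bind_cols(tibble::tibble(bout_id = batch$bout_id[i]), res$errors)
  })
}

#' Median absolute percent error per metric over a batch evaluation
#'
#' @param evaluation A tibble from [evaluate_batch()].
#' @return A tibble with `metric`, `n`, `mdape` (plus quartiles).
#' @export
batch_mdape <- function(evaluation) {
  evaluation |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(~ median_errors(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("metric", "n", "mdape", "mdape_q1", "mdape_q3", "mdae")
}
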