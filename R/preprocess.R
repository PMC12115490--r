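#' Detrend and bandpass a recording
#'
#' Removes the mean and applies a zero-phase 4th-order Butterworth bandpass
#' (forward-backward filtering) to every axis, retaining components between
#' `band_low` and `band_high`. The band defaults to 0.3–4.6 Hz, covering
#' physiologic step cadences while suppressing baseline drift below and
#' non-gait vibration above. Zero-phase filtering keeps step peaks aligned
#' with second boundaries, which matters for the per-second activity gate.
#'
#' @param rec An [accel_recording()].
#' @param band_low,band_high Band edges in Hz.
#' @param order Butterworth prototype order.
#' @return A filtered [accel_recording()] of the same length.
#' @export
preprocess_signal <- function(rec, band_low = 0.3, band_high = 4.6,
                              order = 4) {
  fs <- sample_rate(rec)
  if (fs <= 2 * band_high) {
    abort(sprintf("Nyquist error: sample rate %.1f Hz must exceed twice the upper band edge (%.1f Hz)",
                  fs, band_high),
          class = "fftgait_nyquist_error")
  }
  if (band_low >= band_high) {
    abort("band_low must be less than band_high", class = "fftgait_spec_error")
  }
  bf <- signal::butter(order, c(band_low, band_high) / (fs / 2), type = "pass")
  out <- rec
  for (axis in c("ax", "ay", "az")) {
    x <- rec[[axis]]
    out[[axis]] <- signal::filtfilt(bf, x - mean(x))
  }
  attr(out, "band") <- c(band_low, band_high)
  out
}

#' Segment a recording into fixed-length analysis windows
#'
#' Cuts the bout into contiguous non-overlapping windows of `window_s`
#' seconds starting at t = 0. A trailing partial window is kept only if it is
#' at least `min_partial_s` long; its true duration is carried through all
#' per-window formulas.
#'
#' @param rec An [accel_recording()] (usually preprocessed).
#' @param window_s Window length in seconds (default 5).
#' @param min_partial_s Minimum trailing-window duration to keep, in seconds.
#' @return A tibble with one row per window: `window` (0-based index),
#'   `start`, `end`, `duration`, `partial`, and a `samples` list column of
#'   anteroposterior values. Attribute `sample_rate` is carried over.
#' @export
segment_windows <- function(rec, window_s = 5, min_partial_s = 1) {
  fs <- sample_rate(rec)
  x <- ap_signal(rec)
  n <- length(x)
  dur <- n / fs
  if (dur < min_partial_s) {
    warn("Recording shorter than the minimum window; returning zero windows")
    out <- tibble::tibble(window = integer(0), start = numeric(0),
                          end = numeric(0), duration = numeric(0),
                          partial = logical(0), samples = list())
    attr(out, "sample_rate") <- fs
    return(out)
  }
  per_win <- round(window_s * fs)
  n_full <- floor(n / per_win)
  starts_idx <- seq_len(n_full) * per_win - per_win + 1
  rows <- lapply(seq_len(n_full), function(i) {
    idx <- starts_idx[i]:(starts_idx[i] + per_win - 1)
    tibble::tibble(window = i - 1L, start = (idx[1] - 1) / fs,
                   end = idx[length(idx)] / fs, duration = window_s,
                   partial = FALSE, samples = list(x[idx]))
  })
  rem <- n - n_full * per_win
  if (rem / fs >= min_partial_s) {
    idx <- (n_full * per_win + 1):n
    rows[[length(rows) + 1]] <- tibble::tibble(
      window = as.integer(n_full), start = (idx[1] - 1) / fs,
      end = idx[length(idx)] / fs, duration = rem / fs,
      partial = TRUE, samples = list(x[idx]))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sample_rate") <- fs
  out
}
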