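#' Detect per-step acceleration peaks in a slow-walk calibration recording
#'
#' Finds one peak per step in the preprocessed SC-L1 (very slow walk) trace:
#' positive local maxima of the anteroposterior signal separated by at least
#' the minimum physiologic step period (1/4.6 s) and with topographic
#' prominence of at least `prominence_frac` of the trace's maximum absolute
#' value. The separation constraint enforces one peak per step; the
#' prominence filter rejects ripple riding on the main step impulse.
#'
#' @param scl1 A preprocessed [accel_recording()] of the slowest calibration
#'   walk, at least 5 s long.
#' @param min_separation Minimum peak separation in seconds.
#' @param prominence_frac Minimum prominence as a fraction of `max(abs(x))`.
#' @return Numeric vector of per-step peak accelerations in G.
#' @export
detect_calibration_peaks <- function(scl1, min_separation = 1 / 4.6,
                                     prominence_frac = 0.10) {
  fs <- sample_rate(scl1)
  x <- ap_signal(scl1)
  if (length(x) / fs < 5) {
    abort("Calibration trace must be at least 5 s long",
          class = "fftgait_calibration_error")
  }
  idx <- local_maxima(x)
  idx <- idx[x[idx] > 0]
  if (length(idx) > 0) {
    prom <- peak_prominence(x, idx)
    keep <- prom >= prominence_frac * max(abs(x))
    idx <- idx[keep]
    # greedy keep-highest under the minimum separation constraint
    ord <- idx[order(x[idx], decreasing = TRUE)]
    sep <- round(min_separation * fs)
    chosen <- integer(0)
    for (i in ord) {
      if (all(abs(chosen - i) >= sep)) chosen <- c(chosen, i)
    }
    idx <- sort(chosen)
  }
  if (length(idx) < 3) {
    abort("Calibration error: fewer than 3 step peaks found",
          class = "fftgait_calibration_error")
  }
  x[idx]
}

# indices of strict-left / non-strict-right local maxima, plateau-deduped
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence: height above the higher of the two saddle minima
# toward the nearest higher point on each side (trace edge counts as a bound)
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l) > 0) {
      min(x[(max(higher_l) + 1):(i - 1)])
    } else if (i > 1) min(left) else h
    right <- x[(i + 1):length(x)]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r) > 0) {
      min(x[i + seq_len(min(higher_r) - 1)])
    } else if (i < length(x)) min(right) else h
    h - max(lo_l, lo_r)
  }, numeric(1))
}

#' Compute the activity threshold from calibration peaks
#'
#' The threshold is the mean plus one standard deviation of the per-step peak
#' accelerations, with the standard deviation in population form (divisor
#' `m`, matching the defining formula).
#'
#' @param peaks Numeric vector of per-step peak accelerations (at least 3).
#' @return A list of class `calibration_profile` with elements `peaks`, `mu`,
#'   `sigma`, `threshold` (all in G) and `m`.
#' @export
#' @examples
#' compute_threshold(c(0.8, 1.0, 1.2))$threshold
compute_threshold <- function(peaks) {
  m <- length(peaks)
  if (m < 3) {
    abort("Need at least 3 calibration peaks", class = "fftgait_calibration_error")
  }
  if (any(!is.finite(peaks)) || any(peaks <= 0)) {
    abort("Calibration peaks must be finite and positive",
          class = "fftgait_calibration_error")
  }
  mu <- mean(peaks)
  sigma <- sqrt(sum((peaks - mu)^2) / m)
  structure(list(peaks = peaks, mu = mu, sigma = sigma,
                 threshold = mu + sigma, m = m),
            class = "calibration_profile")
}

#' Calibrate an activity threshold from an SC-L1 recording
#'
#' Convenience wrapper: preprocesses the recording (unless `preprocessed =
#' TRUE`), detects per-step peaks, and computes the mu + sigma threshold.
#'
#' @param scl1 An [accel_recording()] of the slowest calibration walk.
#' @param preprocessed Set to `TRUE` if `scl1` is already detrended and
#'   bandpassed.
#' @inheritParams preprocess_signal
#' @return A `calibration_profile` (see [compute_threshold()]).
#' @export
calibrate <- function(scl1, preprocessed = FALSE,
                      band_low = 0.3, band_high = 4.6) {
  if (!preprocessed) {
    scl1 <- preprocess_signal(scl1, band_low, band_high)
  }
  compute_threshold(detect_calibration_peaks(scl1))
}

#' Serialize a calibration profile to JSON
#' @param profile A `calibration_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration profile written by [write_calibration()]
#' @param path JSON path.
#' @return A `calibration_profile`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fftgait_io_error")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p[c("peaks", "mu", "sigma", "threshold", "m")],
            class = "calibration_profile")
}

#' Classify each second of a window as active or inactive
#'
#' Cuts a window's samples into consecutive 1 s slices (the last slice of a
#' partial window may be shorter) and marks a slice active when the maximum
#' absolute acceleration within it reaches the threshold.
#'
#' @param samples Numeric vector of preprocessed anteroposterior samples.
#' @param sample_rate Hz.
#' @param threshold Activity threshold in G (positive).
#' @return A list with `active_s` (integer count of active seconds) and
#'   `mask` (logical per second).
#' @export
classify_active_seconds <- function(samples, sample_rate, threshold) {
  if (threshold <= 0) {
    abort("threshold must be positive", class = "fftgait_calibration_error")
  }
  per_sec <- round(sample_rate)
  n <- length(samples)
  n_slices <- ceiling(n / per_sec)
  mask <- vapply(seq_len(n_slices), function(k) {
    i0 <- (k - 1) * per_sec + 1
    max(abs(samples[i0:min(k * per_sec, n)])) >= threshold
  }, logical(1))
  list(active_s = sum(mask), mask = mask)
}
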