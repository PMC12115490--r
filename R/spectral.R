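#' Spectral analysis configuration
#'
#' Holds the cadence-detection rule constants: the physiologic frequency band
#' (0.3–4.6 Hz), the two 60% ratios of the harmonic-disambiguation rule, the
#' zero-padding factor controlling FFT bin spacing, and the magnitude floor
#' below which in-band bins are not treated as peaks.
#'
#' @param band_low,band_high Analysis band edges in Hz.
#' @param freq_ratio The lower peak must sit below `freq_ratio` times the
#'   frequency of the dominant peak for the harmonic rule to consider it.
#' @param mag_ratio The lower peak's magnitude must reach `mag_ratio` times
#'   the dominant peak's magnitude.
#' @param zero_pad_factor Integer zero-padding multiple for the FFT, or
#'   `NULL` to pick the smallest factor giving bin spacing at most 0.05 Hz
#'   (a raw 5 s window has 0.2 Hz bins — too coarse for cadence).
#' @param magnitude_floor Fraction of the spectrum maximum below which a bin
#'   cannot be a candidate peak; keeps noise in silent windows from producing
#'   spurious cadence.
#' @param taper `"none"` (default) or `"hann"`.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(band_low = 0.3, band_high = 4.6,
                            freq_ratio = 0.6, mag_ratio = 0.6,
                            zero_pad_factor = NULL,
                            magnitude_floor = 0.05,
                            taper = c("none", "hann")) {
  taper <- match.arg(taper)
  stopifnot(band_low > 0, band_low < band_high,
            freq_ratio > 0, freq_ratio < 1,
            mag_ratio > 0, mag_ratio < 1,
            magnitude_floor >= 0, magnitude_floor < 1)
  if (!is.null(zero_pad_factor)) {
    stopifnot(zero_pad_factor >= 1, zero_pad_factor == round(zero_pad_factor))
  }
  structure(list(band_low = band_low, band_high = band_high,
                 freq_ratio = freq_ratio, mag_ratio = mag_ratio,
                 zero_pad_factor = zero_pad_factor,
                 magnitude_floor = magnitude_floor, taper = taper),
            class = "spectral_config")
}

#' Magnitude spectrum of one analysis window
#'
#' Removes the window mean, optionally applies a Hann taper, zero-pads so the
#' bin spacing is at most 0.05 Hz, and returns the one-sided FFT magnitude
#' spectrum.
#'
#' @param samples Numeric vector of window samples.
#' @param sample_rate Hz.
#' @param config A [spectral_config()].
#' @return A tibble of class `gait_spectrum` with columns `freq` (Hz) and
#'   `mag` (nonnegative), and attributes `resolution` (Hz per bin) and
#'   `sample_rate`.
#' @export
window_spectrum <- function(samples, sample_rate,
                            config = spectral_config()) {
  if (any(!is.finite(samples))) {
    abort("Non-finite samples in window", class = "fftgait_data_error")
  }
  n <- length(samples)
  stopifnot(n >= sample_rate) # at least 1 s of data
  x <- samples - mean(samples)
  if (config$taper == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  }
  pad <- config$zero_pad_factor %||%
    max(1, ceiling(sample_rate / (0.05 * n)))
  nfft <- pad * n
  mag <- Mod(fft(c(x, numeric(nfft - n))))[seq_len(floor(nfft / 2) + 1)]
  mag <- mag * 2 / n
  res <- sample_rate / nfft
  out <- tibble::tibble(freq = (seq_along(mag) - 1) * res, mag = mag)
  structure(out, class = c("gait_spectrum", class(out)),
            resolution = res, sample_rate = sample_rate)
}

#' Select the step frequency from a window spectrum
#'
#' Candidate peaks are local maxima of the in-band magnitude spectrum whose
#' magnitude reaches `magnitude_floor` times the spectrum maximum. If no
#' candidate exists the step frequency is 0. Otherwise let P be the
#' highest-magnitude candidate and Q the highest-magnitude candidate at a
#' lower frequency than P: when Q sits below `freq_ratio` times P's frequency
#' and its magnitude reaches `mag_ratio` times P's magnitude, Q is selected —
#' this demotes the harmonic peak that running and Trendelenburg-style gaits
#' place near twice the true cadence. Equal-magnitude ties go to the lower
#' frequency.
#'
#' @param spectrum A [window_spectrum()] result.
#' @param config A [spectral_config()].
#' @param details If `TRUE`, return a one-row tibble with the selection
#'   internals instead of a bare number.
#' @return Step frequency in Hz (0 when no in-band peak exists), or a tibble
#'   when `details = TRUE`.
#' @export
select_step_frequency <- function(spectrum, config = spectral_config(),
                                  details = FALSE) {
  freq <- spectrum$freq
  mag <- spectrum$mag
  zero_out <- if (details) {
    tibble::tibble(step_frequency = 0, primary_freq = NA_real_,
                   primary_mag = NA_real_, harmonic_rule = FALSE,
                   n_candidates = 0L)
  } else 0
  gmax <- max(mag)
  if (!is.finite(gmax) || gmax <= 0) return(zero_out)

  in_band <- freq >= config$band_low & freq <= config$band_high
  cand <- local_maxima(mag)
  cand <- cand[in_band[cand] & mag[cand] >= config$magnitude_floor * gmax &
                 mag[cand] > 0]
  if (length(cand) == 0) return(zero_out)

  # dominant peak P; ties broken toward the lower frequency
  p <- cand[order(-mag[cand], freq[cand])][1]
  sel <- p
  harmonic <- FALSE
  lower <- cand[freq[cand] < freq[p]]
  if (length(lower) > 0) {
    q <- lower[order(-mag[lower], freq[lower])][1]
    if (freq[q] < config$freq_ratio * freq[p] &&
        mag[q] >= config$mag_ratio * mag[p]) {
      sel <- q
      harmonic <- TRUE
    }
  }
  if (details) {
    tibble::tibble(step_frequency = freq[sel], primary_freq = freq[p],
                   primary_mag = mag[p], harmonic_rule = harmonic,
                   n_candidates = length(cand))
  } else {
    freq[sel]
  }
}
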