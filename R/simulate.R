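#' Specify a synthetic gait bout
#'
#' Describes a bout as a sequence of walk and rest segments. Walk segments are
#' quasi-sinusoidal at a fixed step frequency with a first and an (optional)
#' second harmonic; rest segments contain only drift and noise. The second
#' harmonic emulates the double-peaked spectra seen in running and
#' Trendelenburg-style gaits, where a spectral peak near twice the step
#' frequency can dominate the fundamental.
#'
#' @param segments Data frame with columns `kind` (`"walk"` or `"rest"`),
#'   `duration` (s), and for walk segments `step_frequency` (Hz, within
#'   0.3–4.6), `amp_fundamental` (G), `amp_harmonic` (G).
#' @param sample_rate Sampling rate in Hz (default 100, a typical phone IMU
#'   rate).
#' @param noise_sd Additive Gaussian noise standard deviation in G, applied to
#'   the whole bout.
#' @param drift_amplitude Amplitude in G of a slow sinusoidal baseline drift.
#' @param drift_period Drift period in seconds (at least 30 s so the drift
#'   falls below the analysis band).
#' @param seed Integer seed; the simulator is deterministic given the spec.
#' @return A list of class `gait_sim_spec`.
#' @export
#' @examples
#' spec <- gait_sim_spec(walk_segment(30, 2.0), seed = 7)
gait_sim_spec <- function(segments,
                          sample_rate = 100,
                          noise_sd = 0,
                          drift_amplitude = 0,
                          drift_period = 60,
                          seed = 1) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("kind", "duration") %in% names(segments)))
  if (!all(segments$kind %in% c("walk", "rest"))) {
    abort("segment kind must be 'walk' or 'rest'", class = "fftgait_spec_error")
  }
  if (any(segments$duration <= 0)) {
    abort("segment durations must be positive", class = "fftgait_spec_error")
  }
  for (col in c("step_frequency", "amp_fundamental", "amp_harmonic")) {
    if (!col %in% names(segments)) segments[[col]] <- 0
    segments[[col]][segments$kind == "rest"] <- 0
  }
  walk <- segments[segments$kind == "walk", ]
  if (nrow(walk) > 0) {
    f <- walk$step_frequency
    if (any(f < 0.3 | f > 4.6)) {
      abort("walk step frequencies must lie in [0.3, 4.6] Hz",
            class = "fftgait_spec_error")
    }
    if (any(walk$amp_fundamental < 0 | walk$amp_harmonic < 0)) {
      abort("amplitudes must be nonnegative", class = "fftgait_spec_error")
    }
  }
  if (noise_sd < 0 || drift_amplitude < 0) {
    abort("noise_sd and drift_amplitude must be nonnegative",
          class = "fftgait_spec_error")
  }
  if (drift_period < 30) {
    abort("drift_period must be at least 30 s", class = "fftgait_spec_error")
  }
  structure(list(segments = segments, sample_rate = sample_rate,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period, seed = as.integer(seed)),
            class = "gait_sim_spec")
}

#' Walk and rest segment helpers
#'
#' @param duration Segment duration in seconds.
#' @param step_frequency Step frequency in Hz (walk segments).
#' @param amp_fundamental Fundamental amplitude in G.
#' @param amp_harmonic Second-harmonic amplitude in G.
#' @return A one-row segment tibble for [gait_sim_spec()].
#' @export
walk_segment <- function(duration, step_frequency,
                         amp_fundamental = 0.5, amp_harmonic = 0.15) {
  tibble::tibble(kind = "walk", duration = duration,
                 step_frequency = step_frequency,
                 amp_fundamental = amp_fundamental,
                 amp_harmonic = amp_harmonic)
}

#' @rdname walk_segment
#' @export
rest_segment <- function(duration) {
  tibble::tibble(kind = "rest", duration = duration,
                 step_frequency = 0, amp_fundamental = 0, amp_harmonic = 0)
}

#' Simulate an accelerometer bout with known ground truth
#'
#' Walk segments produce
#' `z(t) = A1 sin(2 pi f t) + A2 sin(4 pi f t + phi2)` plus drift and noise;
#' rest segments produce drift and noise only. Ground-truth step events are
#' placed at the phase crossings of the fundamental, one step per `1/f`
#' interval of walk time, so a segment of duration `d` contributes
#' `floor(f * d)` steps. True step lengths come from the published step-length
#' equation evaluated at the segment's step frequency for the given subject
#' (or from a `step_length` column supplied in the segment table).
#'
#' @param spec A [gait_sim_spec()].
#' @param subject A [subject_profile()] row (height in m, `dmd` flag).
#' @param coefficients Step-length coefficients used for ground-truth lengths.
#' @return A list with elements `recording` (an [accel_recording()]) and
#'   `truth` (a list of class `gait_truth`: `step_times`, per-`segments`
#'   truth table, `total_steps`, `total_distance`, `duration`, second-wise
#'   `active_mask`, and bout-average cadence, step length, and velocity).
#' @export
simulate_bout <- function(spec, subject,
                          coefficients = step_length_coefficients()) {
  stopifnot(inherits(spec, "gait_sim_spec"))
  fs <- spec$sample_rate
  seg <- spec$segments
  seg$start <- cumsum(c(0, head(seg$duration, -1)))
  total_dur <- sum(seg$duration)
  n <- round(total_dur * fs)
  t <- seq(0, by = 1 / fs, length.out = n)

  z <- numeric(n)
  step_times <- numeric(0)
  truth_rows <- vector("list", nrow(seg))
  withr::with_seed(spec$seed, {
    phi2 <- stats::runif(nrow(seg), 0, 2 * pi)
    for (i in seq_len(nrow(seg))) {
      s <- seg[i, ]
      idx <- which(t >= s$start & t < s$start + s$duration)
      if (s$kind == "walk") {
        tt <- t[idx] - s$start
        z[idx] <- z[idx] +
          s$amp_fundamental * sin(2 * pi * s$step_frequency * tt) +
          s$amp_harmonic * sin(4 * pi * s$step_frequency * tt + phi2[i])
        k <- seq_len(floor(s$step_frequency * s$duration))
        st <- s$start + k / s$step_frequency
        step_times <- c(step_times, st)
        sl <- if ("step_length" %in% names(seg) && is.finite(s$step_length) &&
                    s$step_length > 0) {
          s$step_length
        } else {
          predict_step_length(s$step_frequency, subject$height, subject$dmd,
                              coefficients)
        }
        truth_rows[[i]] <- tibble::tibble(
          kind = "walk", start = s$start, duration = s$duration,
          step_frequency = s$step_frequency, n_steps = length(k),
          step_length = sl, distance = length(k) * sl)
      } else {
        truth_rows[[i]] <- tibble::tibble(
          kind = "rest", start = s$start, duration = s$duration,
          step_frequency = 0, n_steps = 0L, step_length = 0, distance = 0)
      }
    }
    if (spec$drift_amplitude > 0) {
      z <- z + spec$drift_amplitude * sin(2 * pi * t / spec$drift_period)
    }
    if (spec$noise_sd > 0) z <- z + stats::rnorm(n, 0, spec$noise_sd)
  })

  truth_seg <- dplyr::bind_rows(truth_rows)
  sec <- seq_len(ceiling(total_dur)) - 1
  walk_seg <- truth_seg[truth_seg$kind == "walk", ]
  active_mask <- vapply(sec, function(s0) {
    any(pmin(walk_seg$start + walk_seg$duration, s0 + 1) -
          pmax(walk_seg$start, s0) >= 0.5)
  }, logical(1))

  total_steps <- sum(truth_seg$n_steps)
  total_distance <- sum(truth_seg$distance)
  truth <- structure(list(
    step_times = step_times,
    segments = truth_seg,
    total_steps = total_steps,
    total_distance = total_distance,
    duration = total_dur,
    active_mask = active_mask,
    avg_step_frequency = total_steps / total_dur,
    avg_step_length = if (total_steps > 0) total_distance / total_steps else 0,
    avg_step_velocity = total_distance / total_dur
  ), class = "gait_truth")

  rec <- accel_recording(tibble::tibble(t = t, ax = 0, ay = 0, az = z))
  list(recording = rec, truth = truth)
}

#' Simulate a very-slow-walk calibration recording (SC-L1)
#'
#' A single low-cadence walk segment suitable for deriving the activity
#' threshold: each step produces one dominant acceleration peak whose
#' amplitude varies only by the configured noise.
#'
#' @param step_frequency Step frequency in Hz (at most 1.5 for a
#'   calibration-grade slow walk).
#' @param duration Duration in seconds.
#' @param amp_fundamental,amp_harmonic Component amplitudes in G.
#' @param noise_sd Additive noise sd in G.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @return An [accel_recording()].
#' @export
simulate_scl1 <- function(step_frequency = 1.0, duration = 20,
                          amp_fundamental = 0.3, amp_harmonic = 0.05,
                          noise_sd = 0.02, sample_rate = 100, seed = 1) {
  if (step_frequency > 1.5) {
    abort("SC-L1 is a very slow walk: step_frequency must be <= 1.5 Hz",
          class = "fftgait_spec_error")
  }
  spec <- gait_sim_spec(
    walk_segment(duration, step_frequency, amp_fundamental, amp_harmonic),
    sample_rate = sample_rate, noise_sd = noise_sd, seed = seed)
  simulate_bout(spec, subject_profile(height = 1.3, dmd = 0))$recording
}

#' Simulate a batch of validation bouts
#'
#' Generates mixed walk/rest bouts with per-segment cadences drawn uniformly
#' from 1.2–3.0 Hz, total durations of 20–180 s, fundamental-dominant
#' harmonics, additive noise at 20% of the fundamental amplitude, and slow
#' baseline drift — together with a matched SC-L1 calibration recording and a
#' subject of random height (1.0–1.7 m) and DMD status. Each bout's
#' simulation seed is derived deterministically from `seed` and the bout
#' index.
#'
#' @param n_bouts Number of bouts.
#' @param seed Integer master seed.
#' @param sample_rate Hz.
#' @return A tibble with one row per bout: `bout_id`, `subject`, `spec`,
#'   `scl1`, `recording`, `truth` (list columns).
#' @export
simulate_validation_batch <- function(n_bouts = 50, seed = 1,
                                      sample_rate = 100) {
  rows <- vector("list", n_bouts)
  for (i in seq_len(n_bouts)) {
    bout_seed <- (1009 * as.double(seed) + i) %% 2147483647
    params <- withr::with_seed(bout_seed, {
      target_dur <- stats::runif(1, 20, 180)
      segs <- list()
      remaining <- target_dur
      walk_turn <- TRUE
      while (remaining >= 5) {
        if (walk_turn) {
          d <- min(remaining, round(stats::runif(1, 8, 30)))
          segs[[length(segs) + 1]] <- walk_segment(
            d, stats::runif(1, 1.2, 3.0),
            amp_fundamental = 0.5,
            amp_harmonic = stats::runif(1, 0.1, 0.3))
        } else {
          d <- min(remaining, round(stats::runif(1, 3, 10)))
          segs[[length(segs) + 1]] <- rest_segment(d)
        }
        remaining <- remaining - d
        walk_turn <- !walk_turn
      }
      list(segments = dplyr::bind_rows(segs),
           height = stats::runif(1, 1.0, 1.7),
           dmd = stats::rbinom(1, 1, 0.4))
    })
    spec <- gait_sim_spec(params$segments, sample_rate = sample_rate,
                          noise_sd = 0.1, drift_amplitude = 0.05,
                          drift_period = 60, seed = bout_seed)
    subject <- subject_profile(paste0("sim", i), params$height, params$dmd)
    sim <- simulate_bout(spec, subject)
    scl1 <- simulate_scl1(sample_rate = sample_rate,
                          seed = (bout_seed + 7) %% 2147483647)
    rows[[i]] <- tibble::tibble(
      bout_id = i, subject = list(subject), spec = list(spec),
      scl1 = list(scl1), recording = list(sim$recording),
      truth = list(sim$truth))
  }
  dplyr::bind_rows(rows)
}
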