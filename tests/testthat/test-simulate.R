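td <- function() subject_profile(height = 1.3, dmd = 0)

test_that("ground-truth step counts follow frequency x duration", {
  spec <- gait_sim_spec(walk_segment(30, 2.0), seed = 1)
  sim <- simulate_bout(spec, td())
  expect_equal(sim$truth$total_steps, 60)
  expect_equal(length(sim$truth$step_times), 60)
  expect_equal(sim$truth$total_distance,
               60 * predict_step_length(2.0, 1.3, 0))
})

test_that("rest-only bouts have zero steps and an all-inactive mask", {
  sim <- simulate_bout(gait_sim_spec(rest_segment(10), noise_sd = 0.01,
                                     seed = 2), td())
  expect_equal(sim$truth$total_steps, 0)
  expect_false(any(sim$truth$active_mask))
  expect_equal(length(sim$truth$active_mask), 10)
})

test_that("simulation is deterministic given the seed", {
  spec <- gait_sim_spec(walk_segment(10, 1.8), noise_sd = 0.1,
                        drift_amplitude = 0.05, seed = 42)
  a <- simulate_bout(spec, td())
  b <- simulate_bout(spec, td())
  expect_identical(a$recording$az, b$recording$az)
  spec2 <- gait_sim_spec(walk_segment(10, 1.8), noise_sd = 0.1,
                         drift_amplitude = 0.05, seed = 43)
  expect_false(identical(a$recording$az,
                         simulate_bout(spec2, td())$recording$az))
})

test_that("out-of-band walk frequencies are rejected", {
  expect_error(gait_sim_spec(walk_segment(10, 5.0)),
               class = "fftgait_spec_error")
  expect_error(gait_sim_spec(walk_segment(10, 0.2)),
               class = "fftgait_spec_error")
})

test_that("spectral fidelity: dominant bin lies at f when the fundamental dominates", {
  for (f in c(0.8, 1.7, 2.9)) {
    sim <- simulate_bout(gait_sim_spec(
      walk_segment(20, f, amp_fundamental = 0.5, amp_harmonic = 0.2),
      seed = 5), td())
    w <- segment_windows(sim$recording)
    sp <- window_spectrum(w$samples[[2]], 100)
    expect_lt(abs(sp$freq[which.max(sp$mag)] - f),
              attr(sp, "resolution") + 1e-9)
  }
})

test_that("harmonic-dominant walks place the dominant bin at 2f", {
  f <- 1.4
  sim <- simulate_bout(gait_sim_spec(
    walk_segment(20, f, amp_fundamental = 0.3, amp_harmonic = 0.45),
    seed = 6), td())
  w <- segment_windows(sim$recording)
  sp <- window_spectrum(w$samples[[2]], 100)
  expect_lt(abs(sp$freq[which.max(sp$mag)] - 2 * f),
            attr(sp, "resolution") + 1e-9)
})

test_that("noiseless SC-L1 has one equal-amplitude peak per step", {
  scl1 <- simulate_scl1(step_frequency = 1.0, duration = 20,
                        amp_fundamental = 0.3, amp_harmonic = 0,
                        noise_sd = 0, seed = 3)
  # oracle: brute-force local-maximum scan on the positive-going trace
  oracle_n <- length(brute_local_maxima(pmax(scl1$az, 0)))
  peaks <- detect_calibration_peaks(preprocess_signal(scl1))
  expect_equal(length(peaks), 20)
  expect_equal(oracle_n, 20)
  # interior peaks equal; the first/last carry zero-phase filter edge effects
  interior <- peaks[3:18]
  expect_lt(diff(range(interior)) / mean(interior), 0.05)
})

test_that("SC-L1 rejects non-slow cadences", {
  expect_error(simulate_scl1(step_frequency = 2.5),
               class = "fftgait_spec_error")
})

test_that("validation batches are reproducible and respect stated ranges", {
  b1 <- simulate_validation_batch(n_bouts = 3, seed = 9)
  b2 <- simulate_validation_batch(n_bouts = 3, seed = 9)
  expect_identical(b1$recording[[2]]$az, b2$recording[[2]]$az)
  for (i in 1:3) {
    segs <- b1$spec[[i]]$segments
    walk <- segs[segs$kind == "walk", ]
    expect_true(all(walk$step_frequency >= 1.2 & walk$step_frequency <= 3.0))
    expect_true(all(walk$amp_harmonic < walk$amp_fundamental))
    dur <- sum(segs$duration)
    expect_true(dur >= 15 && dur <= 180)
    expect_true(b1$subject[[i]]$height >= 1.0 &&
                  b1$subject[[i]]$height <= 1.7)
  }
})
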