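# two-tone spectrum built directly on a fine grid, for rule-level tests
make_spectrum <- function(freqs, mags, res = 0.025, fmax = 50) {
  grid <- seq(0, fmax, by = res)
  mag <- numeric(length(grid))
  for (i in seq_along(freqs)) {
    k <- which.min(abs(grid - freqs[i]))
    mag[k] <- mags[i]
  }
  structure(tibble::tibble(freq = grid, mag = mag),
            class = c("gait_spectrum", "tbl_df", "tbl", "data.frame"),
            resolution = res, sample_rate = 2 * fmax)
}

test_that("window spectra locate tones, scale linearly, and handle silence", {
  rec <- tone_rec(2.0, amp = 1, duration = 5)
  sp <- window_spectrum(rec$az, 100)
  expect_lte(attr(sp, "resolution"), 0.05)
  expect_lt(abs(sp$freq[which.max(sp$mag)] - 2.0), 0.05)

  sp3 <- window_spectrum(3 * rec$az, 100)
  expect_equal(sp3$mag, 3 * sp$mag, tolerance = 1e-9)

  sp0 <- window_spectrum(rep(0, 500), 100)
  expect_true(all(sp0$mag == 0))
  expect_error(window_spectrum(c(rep(0, 499), NA), 100),
               class = "fftgait_data_error")
})

test_that("an all-zero window yields step frequency 0", {
  expect_identical(select_step_frequency(window_spectrum(rep(0, 500), 100)),
                   0)
})

test_that("out-of-band peaks yield step frequency 0", {
  sp <- make_spectrum(c(0.1, 6.0), c(1, 0.8))
  expect_identical(select_step_frequency(sp), 0)
})

test_that("the 60%/60% rule selects the fundamental and rejects weak ones", {
  # 1.2 Hz (0.9) vs 2.4 Hz (1.0): 1.2 < 0.6*2.4 and 0.9 >= 0.6 -> fundamental
  expect_equal(select_step_frequency(make_spectrum(c(1.2, 2.4), c(0.9, 1.0))),
               1.2)
  # magnitude condition fails: 0.5 < 0.6 -> keep the dominant 3.0 Hz peak
  expect_equal(select_step_frequency(make_spectrum(c(1.5, 3.0), c(0.5, 1.0))),
               3.0)
  # frequency condition fails (2.0 not < 0.6*3.0) -> keep dominant
  expect_equal(select_step_frequency(make_spectrum(c(2.0, 3.0), c(0.9, 1.0))),
               3.0)
  det <- select_step_frequency(make_spectrum(c(1.2, 2.4), c(0.9, 1.0)),
                               details = TRUE)
  expect_true(det$harmonic_rule)
  expect_equal(det$primary_freq, 2.4)
})

test_that("selection is scale invariant and ties go to the lower frequency", {
  sp <- make_spectrum(c(1.2, 2.4), c(0.9, 1.0))
  for (c0 in c(0.01, 1, 250)) {
    sp_s <- sp
    sp_s$mag <- sp_s$mag * c0
    expect_equal(select_step_frequency(sp_s), 1.2)
  }
  # exact tie at distant frequencies: lower one wins as peak P
  expect_equal(select_step_frequency(make_spectrum(c(2.0, 3.9), c(1, 1))),
               2.0)
})

test_that("selected frequency is always 0 or inside the band", {
  set.seed(31)
  for (i in 1:40) {
    z <- rnorm(500, 0, 0.05)
    sf <- select_step_frequency(window_spectrum(z, 100))
    expect_true(sf == 0 || (sf >= 0.3 && sf <= 4.6))
  }
})

test_that("noiseless walks are recovered within one bin across the band", {
  for (f in seq(0.5, 4.0, by = 0.5)) {
    sim <- simulate_bout(gait_sim_spec(
      walk_segment(20, f, amp_fundamental = 0.5, amp_harmonic = 0.2),
      seed = 13), subject_profile(height = 1.3, dmd = 0))
    w <- segment_windows(preprocess_signal(sim$recording))
    sp <- window_spectrum(w$samples[[2]], 100)
    expect_lt(abs(select_step_frequency(sp) - f),
              attr(sp, "resolution") + 1e-9)
  }
})

test_that("second-harmonic-dominant gaits resolve to f, not 2f", {
  # A2 > A1 >= 0.6 A2: the stimulus the rule exists for
  for (f in c(1.0, 1.6, 2.2)) {
    sim <- simulate_bout(gait_sim_spec(
      walk_segment(20, f, amp_fundamental = 0.35, amp_harmonic = 0.5),
      seed = 17), subject_profile(height = 1.3, dmd = 0))
    w <- segment_windows(preprocess_signal(sim$recording))
    sp <- window_spectrum(w$samples[[2]], 100)
    expect_lt(abs(select_step_frequency(sp) - f),
              attr(sp, "resolution") + 1e-9)
  }
})
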