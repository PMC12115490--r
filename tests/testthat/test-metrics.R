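td13 <- function() subject_profile(height = 1.30, dmd = 0)

test_that("the per-window metric chain follows the printed formulas", {
  m <- window_metrics(5, 4, 2.0, td13())
  sl <- predict_step_length(2.0, 1.30, 0)
  expect_equal(m$steps, 8)
  expect_equal(m$step_length, sl)
  expect_equal(m$distance, 8 * sl)       # ~4.37 m
  expect_equal(m$velocity, 8 * sl / 4)   # ~1.092 m/s
  expect_equal(m$distance, 4.37, tolerance = 0.01)
  expect_equal(m$velocity, 1.092, tolerance = 0.01)

  # sf = 0 forces the all-zero estimate
  z <- window_metrics(5, 3, 0, td13())
  expect_equal(c(z$steps, z$distance, z$velocity, z$step_length),
               c(0, 0, 0, 0))
  expect_equal(window_metrics(5, 5, 2, td13())$steps, 10)
})

test_that("bout summaries use the total-duration averaging convention", {
  est <- window_metrics(5, 4, 2.0, td13())
  est$window <- 0L; est$start <- 0; est$partial <- FALSE
  s <- summarize_bout(est)
  expect_equal(s$avg_step_velocity, est$distance / 5) # 4.37/5 ~ 0.874
  expect_equal(s$avg_step_velocity, 0.874, tolerance = 0.01)
  expect_equal(s$avg_step_frequency, 8 / 5)
  s_active <- summarize_bout(est, velocity_denominator = "active")
  expect_equal(s_active$avg_step_velocity, est$distance / 4)
})

test_that("totals are additive and averages invariant under duplication", {
  est <- window_metrics(c(5, 5), c(4, 4), c(2.0, 2.0), td13())
  one <- summarize_bout(est[1, ])
  two <- summarize_bout(est)
  expect_equal(two$total_steps, 2 * one$total_steps)
  expect_equal(two$total_distance, 2 * one$total_distance)
  expect_equal(two$avg_step_velocity, one$avg_step_velocity)
  expect_equal(two$avg_step_length, one$avg_step_length)
  expect_equal(two$total_distance, sum(est$distance)) # exact conservation
})

test_that("an all-inactive bout summarizes to zeros", {
  est <- window_metrics(c(5, 5), c(0, 0), c(0, 0), td13())
  s <- summarize_bout(est)
  expect_equal(s$total_steps, 0)
  expect_equal(s$avg_step_length, 0)
  expect_equal(s$p95_step_velocity, 0)
  expect_error(summarize_bout(est[0, ]), class = "fftgait_empty_error")
})

test_that("velocity percentiles are bounded by the window maximum", {
  est <- window_metrics(rep(5, 4), c(5, 4, 3, 5), c(2.4, 1.6, 2.0, 2.8),
                        td13())
  s <- summarize_bout(est)
  expect_lte(s$p95_step_velocity, max(est$velocity))
  expect_lte(s$avg_step_velocity, max(est$velocity))
})

test_that("timelines accumulate distance monotonically", {
  est <- window_metrics(rep(5, 3), c(5, 0, 5), c(2.0, 0, 2.0), td13())
  est$start <- c(0, 5, 10)
  tl <- export_timeline(est)
  d1 <- est$distance[1]
  expect_equal(tl$cumulative_distance, c(d1, d1, d1 + est$distance[3]))
  expect_true(all(diff(tl$cumulative_distance) >= 0))

  path <- withr::local_tempfile(fileext = ".csv")
  export_timeline(est, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$cumulative_distance, tl$cumulative_distance,
               tolerance = 1e-6)
})

test_that("a constant 6-min walk yields cumulative distance near truth", {
  sim <- simulate_bout(gait_sim_spec(walk_segment(360, 2.0), noise_sd = 0.05,
                                     seed = 19), td13())
  res <- run_pipeline(sim$recording, td13(),
                      scl1 = simulate_scl1(seed = 20), truth = sim$truth)
  tl <- res$timeline
  expect_lt(abs(tail(tl$cumulative_distance, 1) - sim$truth$total_distance) /
              sim$truth$total_distance, 0.10)
  expect_lt(abs(res$summary$total_steps - sim$truth$total_steps) /
              sim$truth$total_steps, 0.05)
})
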