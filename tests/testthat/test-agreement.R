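pairs_df <- function(x, y) tibble::tibble(reference = x, estimate = y)

test_that("percentage Bland-Altman matches hand values and is antisymmetric", {
  d <- pairs_df(rep(100, 5), rep(102, 5))
  ba <- bland_altman_percent(d)
  expect_equal(ba$mean_pct_diff, 200 / 101, tolerance = 1e-9) # 1.9802
  expect_equal(ba$sd_pct_diff, 0)
  expect_equal(ba$loa_low, ba$loa_high)

  ident <- bland_altman_percent(pairs_df(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(c(ident$mean_pct_diff, ident$loa_low, ident$loa_high),
               c(0, 0, 0))

  set.seed(41)
  x <- runif(20, 50, 150); y <- x * runif(20, 0.9, 1.1)
  expect_equal(bland_altman_percent(pairs_df(x, y))$mean_pct_diff,
               -bland_altman_percent(pairs_df(y, x))$mean_pct_diff)
  expect_error(bland_altman_percent(pairs_df(c(1, -1, 2), c(-1, 1, 2))),
               class = "fftgait_domain_error")
})

test_that("Passing-Bablok handles identity, scaling, and the worked example", {
  x <- as.numeric(1:10)
  pb1 <- passing_bablok(pairs_df(x, x))
  expect_equal(pb1$slope, 1)
  expect_equal(pb1$intercept, 0)
  pb2 <- passing_bablok(pairs_df(x, 2 * x))
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 0)

  # brute-force enumeration of the 6 pairwise slopes as oracle
  xx <- c(1, 2, 3, 4); yy <- c(1, 2.1, 2.9, 4.2)
  oracle <- brute_passing_bablok(xx, yy)
  pb <- passing_bablok(pairs_df(xx, yy))
  expect_equal(pb$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(pb$intercept, oracle$intercept, tolerance = 1e-9)
  expect_equal(pb$slope, 1.0583, tolerance = 1e-4)
  expect_equal(pb$intercept, -0.0458, tolerance = 1e-3)

  expect_error(passing_bablok(pairs_df(rep(1, 5), 1:5)),
               class = "fftgait_domain_error")
})

test_that("Passing-Bablok is scale equivariant", {
  set.seed(42)
  x <- runif(12, 1, 10); y <- 1.1 * x + rnorm(12, 0, 0.1)
  pb <- passing_bablok(pairs_df(x, y))
  pb_scaled <- passing_bablok(pairs_df(3 * x, 3 * y))
  expect_equal(pb_scaled$slope, pb$slope, tolerance = 1e-9)
  expect_equal(pb_scaled$intercept, 3 * pb$intercept, tolerance = 1e-9)
})

test_that("Lin's CCC matches hand moments and its known properties", {
  expect_equal(lins_ccc(pairs_df(c(1, 2, 3), c(2, 3, 4)))$ccc, 4 / 7,
               tolerance = 1e-9)
  expect_equal(lins_ccc(pairs_df(c(1, 2, 3), c(1, 2, 3)))$ccc, 1)
  expect_lt(lins_ccc(pairs_df(c(1, 2, 3), c(3, 2, 1)))$ccc, 0)

  # |ccc| <= |pearson r|, equality iff matched moments
  set.seed(43)
  for (i in 1:20) {
    x <- rnorm(10); y <- 0.5 * x + rnorm(10, 1, 0.5)
    cc <- lins_ccc(pairs_df(x, y))$ccc
    expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
  }
  expect_error(lins_ccc(pairs_df(rep(1, 4), rep(1, 4))),
               class = "fftgait_domain_error")
})

test_that("median errors match two-point hand values and degenerate cases", {
  me <- median_errors(pairs_df(c(10, 20), c(11, 19)))
  expect_equal(me$mdae, 1)
  expect_equal(me$mdape, 7.5)

  exact <- median_errors(pairs_df(c(5, 6, 7), c(5, 6, 7)))
  expect_equal(c(exact$mdae, exact$mdape), c(0, 0))

  const <- median_errors(pairs_df(c(10, 10, 10), c(12, 12, 12)))
  expect_equal(c(const$mdae, const$mdae_q1, const$mdae_q3), c(2, 2, 2))

  expect_warning(z <- median_errors(pairs_df(c(0, 10, 20), c(1, 11, 19))))
  expect_equal(z$n_zero_ref_excluded, 1)
})

test_that("all four statistics agree with brute force on random instances", {
  set.seed(44)
  n_trials <- 1000
  for (i in seq_len(n_trials)) {
    n <- sample(4:12, 1)
    x <- round(runif(n, 1, 20), 2)
    y <- round(x * runif(1, 0.7, 1.3) + rnorm(n, 0, 0.5), 2)
    if (length(unique(x)) < 2) next
    d <- pairs_df(x, y)
    oracle <- brute_passing_bablok(x, y)
    pb <- passing_bablok(d)
    expect_equal(pb$slope, oracle$slope, tolerance = 1e-12)
    expect_equal(pb$intercept, oracle$intercept, tolerance = 1e-12)
    expect_equal(lins_ccc(d)$ccc, brute_ccc(x, y), tolerance = 1e-12)
    expect_equal(median_errors(d)$mdape, brute_mdape(x, y),
                 tolerance = 1e-12)
    expect_equal(bland_altman_percent(d)$mean_pct_diff,
                 mean(100 * (y - x) / ((x + y) / 2)), tolerance = 1e-12)
  }
})

test_that("acceptance flags implement the published bands", {
  strong <- tibble::tibble(slope = 1.0, slope_low = 0.99, slope_high = 1.01,
                           intercept = 0, intercept_low = -0.01,
                           intercept_high = 0.01, ccc = 0.999)
  f <- acceptance_flags(strong, max_reference = 100)
  expect_true(all(f$pb_strong, f$pb_slope_acceptable,
                  f$pb_intercept_acceptable, f$ccc_strong))

  mid <- tibble::tibble(slope = 1.05, slope_low = 1.02, slope_high = 1.09,
                        intercept = 1.5, intercept_low = 0.5,
                        intercept_high = 2.5, ccc = 0.93)
  fm <- acceptance_flags(mid, max_reference = 100)
  expect_false(fm$pb_strong)
  expect_true(fm$pb_slope_acceptable)
  expect_true(fm$pb_intercept_acceptable)
  expect_false(fm$ccc_strong)
  expect_true(fm$ccc_acceptable)

  bad <- tibble::tibble(slope = 1.2, slope_low = 1.15, slope_high = 1.25,
                        intercept = 5, intercept_low = 4, intercept_high = 6,
                        ccc = 0.85)
  fb <- acceptance_flags(bad, max_reference = 100)
  expect_false(any(fb$pb_strong, fb$pb_slope_acceptable,
                   fb$pb_intercept_acceptable, fb$ccc_acceptable))
})

test_that("the combined agreement report assembles and tidies", {
  set.seed(45)
  x <- runif(30, 50, 400)
  y <- x * 1.02 + rnorm(30, 0, 5)
  rep <- agreement_report(pairs_df(x, y), metric = "distance", units = "m")
  expect_s3_class(rep, "agreement_report")
  expect_true(all(c("slope", "ccc", "mdape", "pb_strong") %in% names(rep)))
  long <- tidy(rep)
  expect_true(all(c("statistic", "value") %in% names(long)))
})
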