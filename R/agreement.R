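#' Percentage Bland–Altman analysis
#'
#' Differences are expressed as percentages of the pair mean,
#' `100 (estimate - reference) / ((estimate + reference) / 2)`, so that
#' agreement limits scale with the magnitude of cyclical measures such as
#' step counts. Positive bias means overestimation. The mean percentage
#' difference carries a normal-theory 95% CI (sd/sqrt(n)); limits of
#' agreement are mean +/- 1.96 sd.
#'
#' @param data Data frame of paired measurements.
#' @param reference,estimate Columns holding the reference (ground-truth) and
#'   estimated values (tidy-eval; defaults to columns named `reference` and
#'   `estimate`).
#' @param conf_level Confidence level for the mean-difference CI.
#' @return One-row tibble: `n`, `mean_pct_diff`, `ci_low`, `ci_high`,
#'   `sd_pct_diff`, `loa_low`, `loa_high`.
#' @export
#' @examples
#' d <- data.frame(reference = c(100, 200, 150), estimate = c(102, 198, 151))
#' bland_altman_percent(d)
bland_altman_percent <- function(data, reference = reference,
                                 estimate = estimate, conf_level = 0.95) {
  x <- dplyr::pull(data, {{ reference }})
  y <- dplyr::pull(data, {{ estimate }})
  check_paired(x, y)
  pm <- (x + y) / 2
  if (any(pm == 0)) {
    abort(paste0("Pair mean of zero at pair ", which(pm == 0)[1],
                 ": percentage difference undefined"),
          class = "fftgait_domain_error")
  }
  d <- 100 * (y - x) / pm
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(n = n, mean_pct_diff = m,
                 ci_low = m - z * s / sqrt(n), ci_high = m + z * s / sqrt(n),
                 sd_pct_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Passing–Bablok regression
#'
#' Nonparametric slope and intercept estimates robust to measurement error
#' in both variables. The slope is the shifted median of all pairwise
#' slopes: i < j pairs with equal x and equal y are excluded, slopes exactly
#' equal to -1 are excluded, and the median index is offset by K, the number
#' of slopes below -1. The intercept is `median(y - slope * x)`. Confidence
#' intervals use the large-sample rank-based normal approximation.
#'
#' @inheritParams bland_altman_percent
#' @return One-row tibble: `n`, `slope`, `slope_low`, `slope_high`,
#'   `intercept`, `intercept_low`, `intercept_high`.
#' @export
#' @examples
#' d <- data.frame(reference = 1:10, estimate = 1:10)
#' passing_bablok(d) # slope 1, intercept 0
passing_bablok <- function(data, reference = reference, estimate = estimate,
                           conf_level = 0.95) {
  x <- dplyr::pull(data, {{ reference }})
  y <- dplyr::pull(data, {{ estimate }})
  check_paired(x, y, min_n = 4)
  if (length(unique(x)) == 1) {
    abort("Degenerate input: all reference values identical",
          class = "fftgait_domain_error")
  }
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- !(dx == 0 & dy == 0)
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  s <- s[s != -1]
  s <- sort(s)
  nn <- length(s)
  if (nn == 0) {
    abort("No valid pairwise slopes", class = "fftgait_domain_error")
  }
  k <- sum(s < -1)
  b <- shifted_median(s, k)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nn - ci) / 2)
  m2 <- nn - m1 + 1
  b_low <- s[clamp_idx(m1 + k, nn)]
  b_high <- s[clamp_idx(m2 + k, nn)]
  tibble::tibble(n = n, slope = b,
                 slope_low = b_low, slope_high = b_high,
                 intercept = median(y - b * x),
                 intercept_low = median(y - b_high * x),
                 intercept_high = median(y - b_low * x))
}

shifted_median <- function(s, k) {
  n <- length(s)
  if (n %% 2 == 1) {
    s[clamp_idx((n + 1) / 2 + k, n)]
  } else {
    (s[clamp_idx(n / 2 + k, n)] + s[clamp_idx(n / 2 + 1 + k, n)]) / 2
  }
}

clamp_idx <- function(i, n) min(max(i, 1), n)

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line, combining precision (Pearson
#' correlation) and accuracy (bias from y = x):
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moment estimators.
#'
#' @inheritParams bland_altman_percent
#' @return One-row tibble: `n`, `ccc`.
#' @export
#' @examples
#' lins_ccc(data.frame(reference = c(1, 2, 3), estimate = c(2, 3, 4)))
lins_ccc <- function(data, reference = reference, estimate = estimate) {
  x <- dplyr::pull(data, {{ reference }})
  y <- dplyr::pull(data, {{ estimate }})
  check_paired(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sxx + syy + (mx - my)^2
  if (denom == 0) {
    abort("Concordance undefined: both series constant with equal means",
          class = "fftgait_domain_error")
  }
  tibble::tibble(n = n, ccc = 2 * sxy / denom)
}

#' Median absolute error and median absolute percent error
#'
#' `MdAE = median(|estimate - reference|)`;
#' `MdAPE = median(100 |estimate - reference| / |reference|)`, excluding
#' zero-reference pairs (with their count reported). Quartiles use type-7
#' linear-interpolation quantiles so values are reproducible bit-for-bit.
#'
#' @inheritParams bland_altman_percent
#' @return One-row tibble: `n`, `mdae`, `mdae_q1`, `mdae_q3`, `mdape`,
#'   `mdape_q1`, `mdape_q3`, `n_zero_ref_excluded`.
#' @export
#' @examples
#' median_errors(data.frame(reference = c(10, 20), estimate = c(11, 19)))
median_errors <- function(data, reference = reference, estimate = estimate) {
  x <- dplyr::pull(data, {{ reference }})
  y <- dplyr::pull(data, {{ estimate }})
  check_paired(x, y, min_n = 2)
  ae <- abs(y - x)
  nz <- x != 0
  if (!all(nz)) {
    warn(sprintf("%d zero-reference pair(s) excluded from MdAPE", sum(!nz)))
  }
  if (!any(nz)) {
    abort("All reference values zero: MdAPE undefined",
          class = "fftgait_domain_error")
  }
  ape <- 100 * ae[nz] / abs(x[nz])
  qa <- quantile(ae, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qp <- quantile(ape, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(x),
                 mdae = qa[2], mdae_q1 = qa[1], mdae_q3 = qa[3],
                 mdape = qp[2], mdape_q1 = qp[1], mdape_q3 = qp[3],
                 n_zero_ref_excluded = sum(!nz))
}

#' Agreement acceptance flags
#'
#' Applies the acceptance bands used for method comparison: strong agreement
#' when the Passing–Bablok slope CI contains 1 and the intercept CI contains
#' 0; acceptable agreement when the slope lies in [0.9, 1.1] and the
#' intercept is within 2% of the maximum observed reference value. Lin's
#' concordance is strong above 0.95 and acceptable above 0.9.
#'
#' @param report A one-row tibble holding at least `slope`, `slope_low`,
#'   `slope_high`, `intercept`, `intercept_low`, `intercept_high`, `ccc`.
#' @param max_reference Maximum observed reference value.
#' @return One-row tibble of logical flags: `pb_strong`,
#'   `pb_slope_acceptable`, `pb_intercept_acceptable`, `ccc_strong`,
#'   `ccc_acceptable`.
#' @export
acceptance_flags <- function(report, max_reference) {
  tibble::tibble(
    pb_strong = report$slope_low <= 1 & report$slope_high >= 1 &
      report$intercept_low <= 0 & report$intercept_high >= 0,
    pb_slope_acceptable = report$slope >= 0.9 & report$slope <= 1.1,
    pb_intercept_acceptable =
      abs(report$intercept) <= 0.02 * abs(max_reference),
    ccc_strong = report$ccc > 0.95,
    ccc_acceptable = report$ccc > 0.9)
}

#' Full agreement report for one metric
#'
#' Combines percentage Bland–Altman, Passing–Bablok, Lin's concordance,
#' MdAE/MdAPE with IQRs, and the acceptance flags into one row, matching the
#' column layout of a method-comparison table.
#'
#' @inheritParams bland_altman_percent
#' @param metric Label for the compared quantity.
#' @param units Unit label.
#' @param max_reference Maximum observed reference value (defaults to
#'   `max(reference)`), used by the intercept acceptance band.
#' @return A one-row tibble of class `agreement_report`.
#' @export
agreement_report <- function(data, reference = reference,
                             estimate = estimate, metric = "metric",
                             units = "", max_reference = NULL) {
  x <- dplyr::pull(data, {{ reference }})
  y <- dplyr::pull(data, {{ estimate }})
  d <- tibble::tibble(reference = x, estimate = y)
  ba <- bland_altman_percent(d)
  pb <- passing_bablok(d)
  cc <- lins_ccc(d)
  me <- median_errors(d)
  rep <- dplyr::bind_cols(
    tibble::tibble(metric = metric, units = units, n = length(x)),
    ba[, -1], pb[, -1], cc[, "ccc"], me[, -1])
  flags <- acceptance_flags(rep, max_reference %||% max(abs(x)))
  out <- dplyr::bind_cols(rep, flags)
  structure(out, class = c("agreement_report", class(out)))
}

#' Tidy an agreement report
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Long tibble with `metric`, `statistic`, `value`.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x),
                  dplyr::across(dplyr::where(is.logical), as.numeric)),
    -c("metric", "units"),
    names_to = "statistic", values_to = "value")
}

check_paired <- function(x, y, min_n = 3) {
  if (length(x) != length(y)) {
    abort("Paired series must have equal length", class = "fftgait_domain_error")
  }
  if (length(x) < min_n) {
    abort(sprintf("Need at least %d pairs", min_n),
          class = "fftgait_domain_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Paired series must be finite", class = "fftgait_data_error")
  }
  invisible(TRUE)
}
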