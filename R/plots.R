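#' Plot a bout timeline
#'
#' Stacked panels over window start time: step frequency, per-window step
#' velocity with a dashed line at the bout's 95th-percentile velocity, and
#' cumulative travel distance (whose slope is velocity).
#'
#' @param object A `gait_timeline` from [export_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gait_timeline
#' @export
autoplot.gait_timeline <- function(object, ...) {
  act <- object$velocity[object$velocity > 0]
  p95 <- if (length(act) > 0) quantile(act, 0.95, type = 7) else NA_real_
  long <- tidyr::pivot_longer(
    object[, c("start", "step_frequency", "velocity", "cumulative_distance")],
    -"start", names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel,
                       levels = c("step_frequency", "velocity",
                                  "cumulative_distance"),
                       labels = c("step frequency (Hz)",
                                  "step velocity (m/s)",
                                  "cumulative distance (m)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_hline(
      data = data.frame(panel = factor("step velocity (m/s)",
                                       levels = levels(long$panel)),
                        value = p95),
      ggplot2::aes(yintercept = .data$value),
      linetype = "dashed", color = "red", na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a window spectrum
#'
#' Magnitude spectrum with the analysis band shaded and the selected step
#' frequency marked.
#'
#' @param object A `gait_spectrum` from [window_spectrum()].
#' @param config A [spectral_config()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gait_spectrum
#' @export
autoplot.gait_spectrum <- function(object, config = spectral_config(), ...) {
  sf <- select_step_frequency(object, config)
  d <- tibble::as_tibble(object)
  d <- d[d$freq <= 2 * config$band_high, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$mag)) +
    ggplot2::annotate("rect", xmin = config$band_low, xmax = config$band_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "green") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = if (sf > 0) sf else NA_real_,
                        linetype = "dashed", color = "red", na.rm = TRUE) +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude (G)",
                  title = if (sf > 0) {
                    sprintf("selected step frequency: %.2f Hz", sf)
                  } else "no in-band peak") +
    ggplot2::theme_minimal()
}

#' Bland–Altman plot of percentage differences
#'
#' Percentage difference of each pair against the pair mean, with the mean
#' difference (solid) and 95% limits of agreement (dashed).
#'
#' @inheritParams bland_altman_percent
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(data, reference = reference,
                              estimate = estimate) {
  x <- dplyr::pull(data, {{ reference }})
  y <- dplyr::pull(data, {{ estimate }})
  ba <- bland_altman_percent(tibble::tibble(reference = x, estimate = y))
  d <- tibble::tibble(pair_mean = (x + y) / 2,
                      pct_diff = 100 * (y - x) / ((x + y) / 2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair_mean, y = .data$pct_diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_pct_diff, color = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "pair mean", y = "% difference (estimate - reference)") +
    ggplot2::theme_minimal()
}
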