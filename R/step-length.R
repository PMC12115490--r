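#' Step-length model coefficients
#'
#' The eight coefficients of the published step-length equation. With
#' u = sqrt(step frequency) and v = 1/sqrt(height), predicted step length is
#'
#'   SL = b_sf u + b_h v + b_sf_h u v + b_0
#'        + dmd (d_0 + d_sf u + d_h v + d_sf_h u v)
#'
#' where `dmd` is 1 for individuals with Duchenne muscular dystrophy and 0
#' for typically developing controls. Defaults are the published values,
#' fitted on 261 multi-speed walking trials of children aged 3–16.
#'
#' @param b_sf,b_h,b_sf_h,b_0 Coefficients of the control (TD) part.
#' @param d_0,d_sf,d_h,d_sf_h Coefficients of the DMD interaction part.
#' @return A named numeric vector of class `step_length_coefficients`.
#' @export
#' @examples
#' step_length_coefficients()
step_length_coefficients <- function(b_sf = 3.33758,
                                     b_h = 2.442582,
                                     b_sf_h = -3.072612,
                                     b_0 = -2.505019,
                                     d_0 = 1.87948,
                                     d_sf = -1.689478,
                                     d_h = -1.865428,
                                     d_sf_h = 1.664073) {
  co <- c(b_sf = b_sf, b_h = b_h, b_sf_h = b_sf_h, b_0 = b_0,
          d_0 = d_0, d_sf = d_sf, d_h = d_h, d_sf_h = d_sf_h)
  if (any(!is.finite(co))) {
    abort("All coefficients must be finite", class = "fftgait_domain_error")
  }
  structure(co, class = "step_length_coefficients")
}

#' Predict step length from cadence, height, and DMD status
#'
#' Evaluates the transformed-covariate step-length model. A step frequency of
#' 0 denotes an inactive window and returns 0 m. Negative predictions
#' (possible at very low cadence with the DMD adjustment) are clamped to 0
#' with a warning.
#'
#' @param step_frequency Steps per second (vectorized, nonnegative).
#' @param height Standing height in meters (positive).
#' @param dmd 0/1 indicator.
#' @param coefficients A [step_length_coefficients()] vector.
#' @return Predicted step length(s) in meters.
#' @export
#' @examples
#' predict_step_length(2.0, 1.30, dmd = 0) # ~0.546 m
predict_step_length <- function(step_frequency, height, dmd = 0,
                                coefficients = step_length_coefficients()) {
  if (any(height <= 0)) {
    abort("height must be positive", class = "fftgait_domain_error")
  }
  if (any(step_frequency < 0)) {
    abort("step_frequency must be nonnegative", class = "fftgait_domain_error")
  }
  co <- coefficients
  u <- sqrt(step_frequency)
  v <- 1 / sqrt(height)
  sl <- co[["b_sf"]] * u + co[["b_h"]] * v + co[["b_sf_h"]] * u * v +
    co[["b_0"]] +
    dmd * (co[["d_0"]] + co[["d_sf"]] * u + co[["d_h"]] * v +
             co[["d_sf_h"]] * u * v)
  sl[step_frequency == 0] <- 0
  if (any(sl < 0)) {
    warn(sprintf("%d negative step-length prediction(s) clamped to 0",
                 sum(sl < 0)))
    sl[sl < 0] <- 0
  }
  unname(sl)
}

#' Fit the eight-term step-length model
#'
#' Least-squares fit of observed step length on the design
#' \{u, v, uv, 1, dmd, dmd u, dmd v, dmd uv\} with u = sqrt(cadence) and
#' v = 1/sqrt(height). This is a fixed-effects fit: the original model used
#' mixed-model regression with within-participant random effects, which
#' cannot be reproduced without participant-level identifiers, and the fit
#' report labels itself accordingly.
#'
#' @param data Data frame with columns `step_frequency` (steps/s, > 0),
#'   `height` (m), `dmd` (0/1), and `step_length` (m, > 0).
#' @param dmd_terms Estimate the four DMD interaction terms (requires both
#'   groups present).
#' @return An object of class `step_length_fit` with elements
#'   `coefficients` (a [step_length_coefficients()] vector), `fit` (the
#'   underlying `lm`), `rmse` (sqrt of mean squared residual, m),
#'   `adj_r_squared`, `n`, and `dmd_terms`. Supports [tidy()], [glance()],
#'   and `predict()`.
#' @export
fit_step_length_model <- function(data, dmd_terms = TRUE) {
  req <- c("step_frequency", "height", "step_length")
  if (dmd_terms) req <- c(req, "dmd")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
          class = "fftgait_schema_error")
  }
  if (nrow(data) < 20) {
    abort("Need at least 20 observations", class = "fftgait_fit_error")
  }
  if (any(data$step_frequency <= 0) || any(data$step_length <= 0)) {
    abort("step_frequency and step_length must be positive for fitting",
          class = "fftgait_fit_error")
  }
  d <- tibble::tibble(
    y = data$step_length,
    u = sqrt(data$step_frequency),
    v = 1 / sqrt(data$height))
  d$uv <- d$u * d$v
  if (dmd_terms) {
    if (length(unique(data$dmd)) < 2) {
      abort(paste("DMD interaction terms are unidentifiable: only one group",
                  "present (collinear terms: dmd, dmd:u, dmd:v, dmd:uv)"),
            class = "fftgait_fit_error")
    }
    d$dmd <- data$dmd
    d$dmd_u <- d$dmd * d$u
    d$dmd_v <- d$dmd * d$v
    d$dmd_uv <- d$dmd * d$uv
    fit <- lm(y ~ u + v + uv + dmd + dmd_u + dmd_v + dmd_uv, data = d)
  } else {
    fit <- lm(y ~ u + v + uv, data = d)
  }
  cf <- coef(fit)
  if (any(is.na(cf))) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "fftgait_fit_error")
  }
  co <- step_length_coefficients(
    b_sf = cf[["u"]], b_h = cf[["v"]], b_sf_h = cf[["uv"]],
    b_0 = cf[["(Intercept)"]],
    d_0 = if (dmd_terms) cf[["dmd"]] else 0,
    d_sf = if (dmd_terms) cf[["dmd_u"]] else 0,
    d_h = if (dmd_terms) cf[["dmd_v"]] else 0,
    d_sf_h = if (dmd_terms) cf[["dmd_uv"]] else 0)
  structure(list(coefficients = co, fit = fit,
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 adj_r_squared = summary(fit)$adj.r.squared,
                 n = nrow(data), dmd_terms = dmd_terms),
            class = "step_length_fit")
}

#' @export
print.step_length_fit <- function(x, ...) {
  cat("Step-length model (fixed-effects least squares",
      if (x$dmd_terms) "with DMD interaction terms" else "TD terms only",
      ")\n", sep = "")
  cat(sprintf("  n = %d, adj R^2 = %.4f, RMSE = %.4f m\n",
              x$n, x$adj_r_squared, x$rmse))
  print(round(unclass(x$coefficients), 6))
  invisible(x)
}

#' @export
predict.step_length_fit <- function(object, newdata, ...) {
  predict_step_length(newdata$step_frequency, newdata$height,
                      newdata$dmd %||% 0, object$coefficients)
}

#' Tidy a fitted step-length model
#' @param x A `step_length_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy step_length_fit
#' @export
tidy.step_length_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  term_map <- c("(Intercept)" = "b_0", u = "b_sf", v = "b_h", uv = "b_sf_h",
                dmd = "d_0", dmd_u = "d_sf", dmd_v = "d_h", dmd_uv = "d_sf_h")
  tibble::tibble(term = unname(term_map[rownames(s)]),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a fitted step-length model
#' @param x A `step_length_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `adj.r.squared`, `rmse`, `sigma`,
#'   `n`.
#' @method glance step_length_fit
#' @export
glance.step_length_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 rmse = x$rmse, sigma = s$sigma, n = x$n)
}
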