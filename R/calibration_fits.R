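# Calibration analyses of the precursory experiments: linearity OLS,
# sensitivity-decay slope, orientation difference, dose-rate trend.
# Each returns a small S3 object with tidy()/glance() methods.

#' Dose-linearity fit
#'
#' Ordinary least squares of charge on dose. The intercept (in pC) estimates
#' the electrometer offset; the slope (pC/Gy) the sensitivity.
#'
#' @param data Data frame with dose and charge columns.
#' @param dose,charge Column names (defaults `dose_Gy`, `charge_pC`).
#' @return A `linearity_fit` object with `slope_pc_gy`, `intercept_pc`,
#'   `correlation`, and the underlying `lm` fit.
#' @export
#' @examples
#' d <- simulate_linearity(readout_model(), seed = 1)
#' linearity_fit(d)
linearity_fit <- function(data, dose = "dose_Gy", charge = "charge_pC") {
  x <- data[[dose]]; y <- data[[charge]]
  if (length(x) < 3) abort("Need at least 3 dose points for a linearity fit.")
  if (length(unique(x)) < 2) abort("Dose design is rank-deficient (all doses equal).")
  fit <- lm(y ~ x)
  structure(
    list(slope_pc_gy = unname(coef(fit)[2]),
         intercept_pc = unname(coef(fit)[1]),
         correlation = stats::cor(x, y),
         n = length(x), fit = fit),
    class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("<linearity_fit: slope %.1f pC/Gy, intercept %.1f pC, r = %.5f>\n",
              x$slope_pc_gy, x$intercept_pc, x$correlation))
  invisible(x)
}

#' Sensitivity-decay fit
#'
#' Least-squares slope of normalized response versus accumulated dose,
#' rescaled to percent response loss per 100 Gy.
#'
#' @param data Data frame with accumulated dose and normalized response
#'   columns (as from [simulate_decay_study()]).
#' @param accumulated,response Column names.
#' @return A `decay_fit` object with `loss_pct_per_100gy` and its 95% CI.
#' @export
decay_fit <- function(data, accumulated = "accumulated_Gy", response = "response") {
  x <- data[[accumulated]]; y <- data[[response]]
  if (length(x) < 3) abort("Need at least 3 accumulation points.")
  if (any(diff(x) <= 0)) abort("Accumulated dose must be strictly increasing.")
  fit <- lm(y ~ x)
  ci <- confint(fit)["x", ]
  structure(
    list(loss_pct_per_100gy = -unname(coef(fit)[2]) * 1e4,
         conf_low = -ci[2] * 1e4, conf_high = -ci[1] * 1e4,
         n = length(x), fit = fit),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: %.2f %% per 100 Gy (95%% CI %.2f-%.2f)>\n",
              x$loss_pct_per_100gy, x$conf_low, x$conf_high))
  invisible(x)
}

#' Axial versus edge-on orientation difference
#'
#' Normalizes charge per monitor unit to the maximum of all readings (both
#' orientations pooled), then reports the absolute percent difference of the
#' orientation means relative to the axial mean, with a t-based confidence
#' interval on the difference.
#'
#' @param data Data frame as from [simulate_orientation_study()].
#' @param conf_level Confidence level (default 0.95).
#' @return An `orientation_test` object with `difference_pct`, its CI and
#'   the per-orientation normalized means.
#' @export
orientation_difference <- function(data, conf_level = 0.95) {
  stopifnot(all(c("orientation", "charge_pC", "mu") %in% names(data)))
  ratio <- data$charge_pC / data$mu
  norm <- ratio / max(ratio)
  g <- split(norm, data$orientation)
  if (length(g) != 2 || any(vapply(g, length, 1L) < 2)) {
    abort("Need >= 2 replicates in each of two orientations.")
  }
  ax <- g[["axial"]]; eo <- g[["edge_on"]]
  if (mean(ax) == 0) abort("Axial mean response is zero; cannot form a ratio.")
  diff_frac <- (mean(ax) - mean(eo)) / mean(ax)
  se <- sqrt(stats::var(ax) / length(ax) + stats::var(eo) / length(eo)) / mean(ax)
  df <- length(ax) + length(eo) - 2
  tq <- qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(difference_pct = abs(diff_frac) * 100,
         signed_difference_pct = diff_frac * 100,
         conf_low = (diff_frac - tq * se) * 100,
         conf_high = (diff_frac + tq * se) * 100,
         mean_axial = mean(ax), mean_edge_on = mean(eo),
         conf_level = conf_level),
    class = "orientation_test")
}

#' @export
print.orientation_test <- function(x, ...) {
  cat(sprintf("<orientation_test: |difference| %.2f%% (signed %.2f%%, %d%% CI %.2f to %.2f)>\n",
              x$difference_pct, x$signed_difference_pct,
              round(100 * x$conf_level), x$conf_low, x$conf_high))
  invisible(x)
}

#' Dose-rate uniformity test
#'
#' Least-squares slope of normalized response versus dose rate with its
#' confidence interval; the verdict is `"uniform"` when the interval covers
#' zero.
#'
#' @param data Data frame as from [simulate_dose_rate_study()].
#' @param rate,response Column names.
#' @param conf_level Confidence level (default 0.95).
#' @return A `dose_rate_fit` object with `slope_per_cgy_s`, CI, `verdict`.
#' @export
dose_rate_uniformity <- function(data, rate = "dose_rate_cgy_s",
                                 response = "response", conf_level = 0.95) {
  x <- data[[rate]]; y <- data[[response]]
  if (length(x) < 3) abort("Need at least 3 dose rates.")
  fit <- lm(y ~ x)
  ci <- confint(fit, level = conf_level)["x", ]
  structure(
    list(slope_per_cgy_s = unname(coef(fit)[2]),
         conf_low = unname(ci[1]), conf_high = unname(ci[2]),
         verdict = if (ci[1] <= 0 && ci[2] >= 0) "uniform" else "trend",
         conf_level = conf_level, fit = fit),
    class = "dose_rate_fit")
}

#' @export
print.dose_rate_fit <- function(x, ...) {
  cat(sprintf("<dose_rate_fit: slope %.4g per cGy/s (CI %.4g to %.4g) -> %s>\n",
              x$slope_per_cgy_s, x$conf_low, x$conf_high, x$verdict))
  invisible(x)
}
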