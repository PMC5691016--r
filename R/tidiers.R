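# broom-style tidiers for the fitted/comparison objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy linearity_fit
#' @export
tidy.linearity_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept_pc", "slope_pc_gy"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @method glance linearity_fit
#' @export
glance.linearity_fit <- function(x, ...) {
  tibble(slope_pc_gy = x$slope_pc_gy, intercept_pc = x$intercept_pc,
         correlation = x$correlation, n = x$n)
}

#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = "loss_pct_per_100gy", estimate = x$loss_pct_per_100gy,
         conf.low = min(x$conf_low, x$conf_high),
         conf.high = max(x$conf_low, x$conf_high))
}

#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(loss_pct_per_100gy = x$loss_pct_per_100gy, n = x$n)
}

#' @method tidy orientation_test
#' @export
tidy.orientation_test <- function(x, ...) {
  tibble(term = "orientation_difference_pct",
         estimate = x$signed_difference_pct,
         conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @method glance orientation_test
#' @export
glance.orientation_test <- function(x, ...) {
  tibble(difference_pct = x$difference_pct,
         mean_axial = x$mean_axial, mean_edge_on = x$mean_edge_on,
         conf_level = x$conf_level)
}

#' @method tidy dose_rate_fit
#' @export
tidy.dose_rate_fit <- function(x, ...) {
  tibble(term = "slope_per_cgy_s", estimate = x$slope_per_cgy_s,
         conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @method glance dose_rate_fit
#' @export
glance.dose_rate_fit <- function(x, ...) {
  tibble(slope_per_cgy_s = x$slope_per_cgy_s, verdict = x$verdict,
         conf_level = x$conf_level)
}

#' @method tidy ratio_comparison
#' @export
tidy.ratio_comparison <- function(x, ...) x$ratios

#' @method glance ratio_comparison
#' @export
glance.ratio_comparison <- function(x, ...) {
  tibble(distal_ratio_90 = x$distal_ratio_90,
         distal_ratio_95 = x$distal_ratio_95,
         clip_depth_mm = x$clip_depth_mm,
         d50_difference_mm = x$d50_difference_mm)
}

#' @method tidy sobp
#' @export
tidy.sobp <- function(x, ...) x$weights

#' @method glance sobp
#' @export
glance.sobp <- function(x, ...) {
  tibble(n_components = nrow(x$weights), extent_mm = x$extent_mm,
         flatness_pct = x$flatness_pct)
}
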