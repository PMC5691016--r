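# ggplot2 presentations of the result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_vline labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' @method autoplot dose_profile
#' @export
autoplot.dose_profile <- function(object, ...) {
  xlab <- if (profile_axis(object) == "depth") {
    "Depth (mm WED)"
  } else {
    "Transverse position (mm)"
  }
  ggplot(object, aes(x = position_mm, y = dose)) +
    geom_line(...) +
    labs(x = xlab, y = "Relative dose") +
    theme_minimal()
}

#' @method autoplot sobp
#' @export
autoplot.sobp <- function(object, ...) {
  autoplot(object$profile, ...) +
    geom_hline(yintercept = 0.9, linetype = "dashed", colour = "grey50") +
    labs(subtitle = sprintf("90-90%% extent %.1f mm, flatness %.2f%%",
                            object$extent_mm, object$flatness_pct))
}

#' @method autoplot ratio_comparison
#' @export
autoplot.ratio_comparison <- function(object, ...) {
  ggplot(object$ratios, aes(x = depth_mm, y = ratio)) +
    geom_line(...) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    labs(x = "Depth (mm WED)", y = "Dose ratio (diode / reference)") +
    theme_minimal()
}

#' @method autoplot microdose_curve
#' @export
autoplot.microdose_curve <- function(object, ...) {
  ggplot(object, aes(x = depth_mm, y = .data$yD_keV_um)) +
    geom_line(...) + geom_point() +
    labs(x = "Depth (mm WED)",
         y = expression(bar(y)[D] ~ "(keV/" * mu * "m)")) +
    theme_minimal()
}

#' Overlay depth-dose profiles from several modalities
#'
#' @param profiles Named list of depth [dose_profile()]s.
#' @return A ggplot object.
#' @export
plot_depth_dose_comparison <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  df <- dplyr::bind_rows(
    purrr::imap(profiles, function(p, nm) {
      tibble(position_mm = p$position_mm, dose = p$dose, modality = nm)
    })
  )
  ggplot(df, aes(x = position_mm, y = dose, colour = .data$modality)) +
    geom_line() +
    labs(x = "Depth (mm WED)", y = "Relative dose", colour = NULL) +
    theme_minimal()
}
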