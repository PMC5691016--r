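#' Diode-to-reference dose ratio curve
#'
#' Resamples the diode profile onto the reference depth grid by local
#' quadratic interpolation and forms the pointwise relative-dose ratio,
#' restricted to depths where the reference is at least 25% of its maximum
#' and clipped at the reference's distal 25% crossing. Distal-edge ratios
#' are interpolated quadratically at the depths where the reference crosses
#' its distal 90% and 95% levels.
#'
#' @param diode Measured depth [dose_profile()].
#' @param reference Reference depth [dose_profile()] (e.g. chamber scan).
#' @return A `ratio_comparison` object: `ratios` tibble (`depth_mm`,
#'   `ratio`, `reference_dose`), `distal_ratio_90`, `distal_ratio_95`,
#'   `clip_depth_mm`, `d50_difference_mm`.
#' @export
ratio_curve <- function(diode, reference) {
  diode <- as_profile(diode)
  reference <- as_profile(reference)
  lo <- max(min(diode$position_mm), min(reference$position_mm))
  hi <- min(max(diode$position_mm), max(reference$position_mm))
  if (lo >= hi) abort("Profiles have no overlapping depth support.")
  clip <- level_crossing(reference, 0.25, "distal")
  if (is.na(clip)) clip <- hi
  refmax <- max(reference$dose)
  keep <- reference$position_mm >= lo & reference$position_mm <= min(hi, clip) &
    reference$dose >= 0.25 * refmax
  z <- reference$position_mm[keep]
  dref <- reference$dose[keep]
  ddiode <- quad_interp(diode$position_mm, diode$dose, z)
  ratios <- tibble(depth_mm = z, ratio = ddiode / dref, reference_dose = dref)
  r90 <- interp_at_level(ratios[, c("depth_mm", "ratio")], reference, 0.90)$value
  r95 <- interp_at_level(ratios[, c("depth_mm", "ratio")], reference, 0.95)$value
  structure(
    list(ratios = ratios,
         distal_ratio_90 = r90,
         distal_ratio_95 = r95,
         clip_depth_mm = clip,
         d50_difference_mm = d50_distal(diode) - d50_distal(reference)),
    class = "ratio_comparison")
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat(sprintf(
    "<ratio_comparison: %d points to %.1f mm; distal ratios %.3f (90%%), %.3f (95%%); dD50 %+.2f mm>\n",
    nrow(x$ratios), x$clip_depth_mm, x$distal_ratio_90, x$distal_ratio_95,
    x$d50_difference_mm))
  invisible(x)
}

#' Misalignment shift sensitivity of a distal falloff
#'
#' Analytic estimate of the relative-dose-ratio change induced by a depth
#' misalignment `shift`, assuming a linear falloff of dose between the
#' distal 95% and 25% crossings and evaluating at the mid-falloff (60%)
#' level: `change = 100 * shift * gradient / 0.6` with
#' `gradient = 0.7 / (z25 - z95)` per mm.
#'
#' @param profile A depth [dose_profile()] with a distal falloff.
#' @param shift Misalignment in mm (>= 0); vectorized.
#' @return Tibble with `shift_mm`, `ratio_change_pct`, and the falloff
#'   geometry (`z95_mm`, `z25_mm`, `gradient_per_mm`).
#' @export
#' @examples
#' p <- pristine_bragg(beam_spec("127MeV", 99.5))
#' shift_sensitivity(p, c(0.4, 0.9))
shift_sensitivity <- function(profile, shift) {
  profile <- as_profile(profile)
  if (any(shift < 0)) abort("`shift` must be >= 0.")
  z95 <- level_crossing(profile, 0.95, "distal")
  z25 <- level_crossing(profile, 0.25, "distal")
  if (is.na(z95) || is.na(z25)) abort("Profile lacks a distal 95%-25% falloff.")
  width <- z25 - z95
  if (width <= 0) abort("Degenerate distal falloff (95% and 25% crossings coincide).")
  g <- 0.70 / width
  tibble(shift_mm = shift,
         ratio_change_pct = 100 * shift * g / 0.60,
         z95_mm = z95, z25_mm = z25, gradient_per_mm = g)
}

# direct (non-linearized) ratio change at the 60% level for a given shift:
# the profile shifted deeper by `shift` plays the reference
shift_ratio_direct <- function(profile, shift) {
  profile <- as_profile(profile)
  z60 <- level_crossing(profile, 0.60, "distal")
  d_at <- function(z) approx(profile$position_mm, profile$dose, xout = z, rule = 2)$y
  100 * (d_at(z60) / d_at(z60 + shift) - 1)
}

#' Per-beam agreement table of D50 and width differences
#'
#' Reproduces the study-style comparison tables: for matched beams measured
#' by several modalities, the per-beam distal D50 (depth profiles) or
#' FWHM/FW90M (lateral profiles) and their signed differences from each
#' non-reference modality to the reference, in mm.
#'
#' @param data Data frame with columns `beam` (label), `modality`, and
#'   `profile` (list-column of [dose_profile()]s).
#' @param reference Modality name to difference against.
#' @return A tibble, one row per beam, with per-modality metrics and signed
#'   `<modality>_minus_<reference>` differences. Beams lacking the reference
#'   modality are an error naming the orphans.
#' @export
agreement_table <- function(data, reference = "markus") {
  stopifnot(all(c("beam", "modality", "profile") %in% names(data)))
  beams <- split(data, data$beam)
  orphans <- names(beams)[!vapply(beams, function(b) reference %in% b$modality, logical(1))]
  if (length(orphans) > 0) {
    abort(sprintf("Beams lacking the '%s' reference modality: %s",
                  reference, paste(orphans, collapse = ", ")))
  }
  rows <- purrr::map(beams, function(b) {
    axis <- profile_axis(b$profile[[1]])
    metric <- if (axis == "depth") {
      vapply(b$profile, d50_distal, numeric(1))
    } else {
      vapply(b$profile, full_width, numeric(1), level = 0.5)
    }
    names(metric) <- b$modality
    ref <- metric[[reference]]
    out <- tibble(beam = b$beam[1])
    for (m in b$modality) out[[paste0(m, "_mm")]] <- metric[[m]]
    for (m in setdiff(b$modality, reference)) {
      out[[paste0(m, "_minus_", reference, "_mm")]] <- metric[[m]] - ref
    }
    out
  })
  dplyr::bind_rows(rows)
}
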