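#' Construct a 1-D dose profile
#'
#' A dose profile is a tibble with columns `position_mm` and `dose` plus
#' metadata attributes: the scan `axis` (`"depth"` for central-axis depth-dose
#' curves in mm water-equivalent depth, `"lateral"` for transverse profiles)
#' and the `normalization` applied so far (`"raw"`, `"max"`, or `"com"`).
#'
#' @param position_mm Numeric vector of positions in mm (strictly increasing).
#'   Depth profiles use mm water-equivalent depth from the phantom surface.
#' @param dose Numeric vector of non-negative (relative) dose values.
#' @param axis `"depth"` or `"lateral"`.
#' @param normalization Normalization already applied: `"raw"`, `"max"`, `"com"`.
#' @return A `dose_profile` tibble.
#' @export
#' @examples
#' p <- dose_profile(0:10, dnorm(0:10, 5, 2), axis = "lateral")
dose_profile <- function(position_mm, dose,
                         axis = c("depth", "lateral"),
                         normalization = "raw") {
  axis <- match.arg(axis)
  position_mm <- as.numeric(position_mm)
  dose <- as.numeric(dose)
  if (length(position_mm) != length(dose)) {
    abort("`position_mm` and `dose` must have the same length.")
  }
  if (length(position_mm) < 2L) abort("A profile needs at least two samples.")
  if (any(!is.finite(position_mm)) || any(!is.finite(dose))) {
    abort("Profile samples must be finite.")
  }
  if (any(diff(position_mm) <= 0)) {
    abort("`position_mm` must be strictly increasing.")
  }
  if (any(dose < 0)) abort("Dose values must be non-negative.")
  out <- tibble(position_mm = position_mm, dose = dose)
  class(out) <- c("dose_profile", class(out))
  attr(out, "axis") <- axis
  attr(out, "normalization") <- normalization
  out
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile: %s axis, %d samples, %s-normalized, [%.2f, %.2f] mm>\n",
              profile_axis(x), nrow(x), attr(x, "normalization") %||% "raw",
              min(x$position_mm), max(x$position_mm)))
  NextMethod()
}

profile_axis <- function(profile) attr(profile, "axis") %||% "depth"

as_profile <- function(x, axis = "depth") {
  if (inherits(x, "dose_profile")) return(x)
  if (is.data.frame(x) && all(c("position_mm", "dose") %in% names(x))) {
    return(dose_profile(x$position_mm, x$dose, axis = axis))
  }
  abort("Expected a `dose_profile` or a data frame with `position_mm` and `dose`.")
}

#' Normalize a dose profile
#'
#' Maximum normalization scales the profile so its largest sample equals 1.
#' Center-of-modulation (COM) normalization, used for modulated depth-dose
#' curves, divides by the interpolated dose at the midpoint of the SOBP
#' 90-90% bounds. Both are pure rescalings.
#'
#' @param profile A [dose_profile()] (or data frame with `position_mm`, `dose`).
#' @param mode `"max"`, `"com"`, or `"raw"` (no-op).
#' @return The rescaled profile with its `normalization` attribute updated.
#' @export
normalize_profile <- function(profile, mode = c("max", "com", "raw")) {
  mode <- match.arg(mode)
  profile <- as_profile(profile)
  if (max(profile$dose) <= 0) abort("Cannot normalize an all-zero profile.")
  scale <- switch(mode,
    raw = 1,
    max = max(profile$dose),
    com = {
      b <- sobp_bounds(profile)
      com_depth <- (b$proximal90_mm + b$distal90_mm) / 2
      approx(profile$position_mm, profile$dose, xout = com_depth)$y
    }
  )
  if (!is.finite(scale) || scale <= 0) {
    abort(sprintf("Normalization scale for mode '%s' is not positive.", mode))
  }
  out <- profile
  out$dose <- profile$dose / scale
  attr(out, "normalization") <- mode
  out
}

#' Median-smooth a profile (explicit, never automatic)
#'
#' Applies a 3-point running median. Extraction functions never smooth
#' silently; call this first when a measured profile is noisy enough to
#' create spurious level crossings.
#'
#' @param profile A [dose_profile()].
#' @return The smoothed profile.
#' @export
smooth_profile <- function(profile) {
  profile <- as_profile(profile)
  out <- profile
  out$dose <- as.numeric(stats::runmed(profile$dose, 3, endrule = "keep"))
  out
}
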