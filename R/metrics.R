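# Profile metric extractors: distal D50, SOBP 90-90 bounds, full widths,
# 20-80% penumbra, quadratic ratio-at-level interpolation.
#
# All level crossings use linear interpolation between the bracketing samples
# and, when noise creates several crossings of the same level, the outermost
# one (farthest from the global maximum). Levels are fractions of the global
# sample maximum, which makes every extractor invariant to the normalization
# mode of the input profile.

# outermost linear-interpolated crossing of `level * max(dose)`
# side: "distal"/"right" searches beyond the max, "proximal"/"left" before it
level_crossing <- function(profile, level, side) {
  x <- profile$position_mm
  d <- profile$dose
  target <- level * max(d)
  im <- which.max(d)
  if (side %in% c("distal", "right")) {
    idx <- im:length(d)
    xx <- x[idx]; dd <- d[idx]
    below <- dd < target
    if (!any(below)) return(NA_real_)
    i <- max(which(below))            # outermost: last sample below target
    # walk back to the last down-crossing at or before i
    j <- max(which(dd[seq_len(i)] >= target))
    if (length(j) == 0 || !is.finite(j)) return(NA_real_)
    x1 <- xx[j]; x2 <- xx[j + 1]; d1 <- dd[j]; d2 <- dd[j + 1]
  } else {
    idx <- seq_len(im)
    xx <- x[idx]; dd <- d[idx]
    below <- dd < target
    if (!any(below)) return(NA_real_)
    i <- min(which(below))            # outermost: first sample below target
    j <- min(which(dd[i:length(dd)] >= target)) + i - 1L
    x1 <- xx[j - 1]; x2 <- xx[j]; d1 <- dd[j - 1]; d2 <- dd[j]
  }
  if (d2 == d1) return((x1 + x2) / 2)
  x1 + (target - d1) * (x2 - x1) / (d2 - d1)
}

#' Distal depth of 50% maximum dose (D50)
#'
#' The depth, distal to the global dose maximum, at which the linearly
#' interpolated dose falls to half the maximum. This is the conventional
#' range metric for pristine and modulated proton depth-dose curves and is
#' invariant to the profile's normalization mode.
#'
#' @param profile A depth [dose_profile()].
#' @return Depth in mm (water-equivalent).
#' @export
#' @examples
#' z <- seq(0, 120, by = 0.5)
#' p <- dose_profile(z, ifelse(z <= 100, 1, pmax(0, 1 - (z - 100) / 10)))
#' d50_distal(p)  # 105
d50_distal <- function(profile) {
  profile <- as_profile(profile)
  z <- level_crossing(profile, 0.5, "distal")
  if (is.na(z)) {
    abort("Dose never falls below 50% of maximum distal to the peak; cannot extract D50.")
  }
  z
}

#' SOBP 90-90% bounds
#'
#' Outermost proximal and distal crossings of 90% of the profile maximum.
#' Their separation is the conventional measure of modulation width for a
#' spread-out Bragg peak and their midpoint defines the center of modulation.
#'
#' @param profile A depth [dose_profile()].
#' @return A one-row tibble with `proximal90_mm`, `distal90_mm`, `extent_mm`.
#' @export
sobp_bounds <- function(profile) {
  profile <- as_profile(profile)
  p <- level_crossing(profile, 0.9, "proximal")
  d <- level_crossing(profile, 0.9, "distal")
  if (is.na(d)) abort("Dose never falls below 90% of maximum on the distal side.")
  if (is.na(p)) p <- profile$position_mm[1]  # profile enters already above 90%
  tibble(proximal90_mm = p, distal90_mm = d, extent_mm = d - p)
}

#' Full width of a profile at a fractional dose level
#'
#' Distance between the outermost interpolated crossings of `level * max`.
#' `full_width(p, 0.5)` is the FWHM and `full_width(p, 0.9)` the FW90M of a
#' lateral profile.
#'
#' @param profile A [dose_profile()].
#' @param level Fraction of the maximum in (0, 1).
#' @return Width in mm.
#' @export
full_width <- function(profile, level = 0.5) {
  profile <- as_profile(profile)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1).")
  }
  l <- level_crossing(profile, level, "left")
  r <- level_crossing(profile, level, "right")
  if (is.na(l) || is.na(r)) {
    abort(sprintf("Profile does not cross %.0f%% of maximum on both sides.", 100 * level))
  }
  r - l
}

#' Lateral penumbra width (20-80%)
#'
#' Distance over which the dose falls between `hi` and `lo` fractions of the
#' maximum at each field edge, reported per side and as the two-side mean.
#'
#' @param profile A lateral [dose_profile()].
#' @param lo,hi Fractional dose levels bounding the penumbra (defaults 0.2, 0.8).
#' @return A one-row tibble with `left_mm`, `right_mm`, `mean_mm`.
#' @export
penumbra_width <- function(profile, lo = 0.2, hi = 0.8) {
  profile <- as_profile(profile)
  stopifnot(lo > 0, hi < 1, lo < hi)
  xs <- lapply(c("left", "right"), function(side) {
    a <- level_crossing(profile, lo, side)
    b <- level_crossing(profile, hi, side)
    if (is.na(a) || is.na(b)) {
      abort(sprintf("Profile does not cross both %.0f%% and %.0f%% on the %s side.",
                    100 * lo, 100 * hi, side))
    }
    abs(a - b)
  })
  tibble(left_mm = xs[[1]], right_mm = xs[[2]], mean_mm = (xs[[1]] + xs[[2]]) / 2)
}

#' Interpolate one curve at the depth where another crosses a distal level
#'
#' Finds the depth at which `curve_b` crosses `level` of its maximum on the
#' distal (or proximal) edge, then evaluates `curve_a` there by quadratic
#' interpolation through the three nearest samples. Used for second-order
#' interpolated detector-ratio values at the distal 90%/95% dose levels.
#' Falls back to linear interpolation, with a warning, when fewer than three
#' samples are available.
#'
#' @param curve_a Profile (or tibble with `position_mm` and a value column)
#'   to evaluate. The second column is used as the value.
#' @param curve_b Reference [dose_profile()] defining the crossing depth.
#' @param level Fractional dose level on `curve_b` (e.g. 0.9, 0.95, 0.5, 0.25).
#' @param edge `"distal"` or `"proximal"` edge of `curve_b`.
#' @return A one-row tibble with `position_mm` (the crossing) and `value`.
#' @export
interp_at_level <- function(curve_a, curve_b, level, edge = c("distal", "proximal")) {
  edge <- match.arg(edge)
  curve_b <- as_profile(curve_b)
  x0 <- level_crossing(curve_b, level, if (edge == "distal") "distal" else "proximal")
  if (is.na(x0)) {
    abort(sprintf("Reference curve has no %s crossing at %.0f%% of maximum.",
                  edge, 100 * level))
  }
  if (!is.data.frame(curve_a) || ncol(curve_a) < 2) {
    abort("`curve_a` must be a data frame with positions and values.")
  }
  xa <- curve_a[[if ("position_mm" %in% names(curve_a)) "position_mm" else 1L]]
  ya <- curve_a[[if ("position_mm" %in% names(curve_a)) setdiff(names(curve_a), "position_mm")[1] else 2L]]
  tibble(position_mm = x0, value = quad_interp(xa, ya, x0))
}

# local quadratic (Lagrange through the three nearest samples); linear fallback
quad_interp <- function(x, y, xout) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warn("Fewer than three samples available; falling back to linear interpolation.")
    return(approx(x, y, xout = xout, rule = 2)$y)
  }
  vapply(xout, function(x0) {
    i <- order(abs(x - x0))[1:3]
    xi <- x[i]; yi <- y[i]
    sum(vapply(1:3, function(k) {
      others <- setdiff(1:3, k)
      yi[k] * prod((x0 - xi[others]) / (xi[k] - xi[others]))
    }, numeric(1)))
  }, numeric(1))
}

#' Summarize a profile's standard dosimetric metrics
#'
#' For depth profiles: distal D50, the 90-90% bounds and extent, and plateau
#' flatness. For lateral profiles: FWHM, FW90M and the mean 20-80% penumbra.
#' Flatness is the maximum deviation from the mean dose over the 90-90%
#' region trimmed at each edge by `max(10%` of the extent, `edge_trim_mm)`,
#' so the unavoidable 0.9 to 1.0 edge ramps are not counted against the
#' plateau.
#'
#' @param profile A [dose_profile()].
#' @param edge_trim_mm Minimum trim applied at each plateau edge for the
#'   flatness window (default 4 mm, two default pullback steps).
#' @return A one-row tibble of metrics appropriate to the profile axis.
#' @export
profile_metrics <- function(profile, edge_trim_mm = 4) {
  profile <- as_profile(profile)
  if (profile_axis(profile) == "lateral") {
    pen <- penumbra_width(profile)
    return(tibble(
      fwhm_mm = full_width(profile, 0.5),
      fw90m_mm = full_width(profile, 0.9),
      penumbra_2080_mm = pen$mean_mm
    ))
  }
  b <- sobp_bounds(profile)
  trim <- max(0.1 * b$extent_mm, edge_trim_mm)
  sel <- profile$position_mm >= b$proximal90_mm + trim &
    profile$position_mm <= b$distal90_mm - trim
  flat <- if (sum(sel) >= 2) {
    m <- mean(profile$dose[sel])
    100 * max(abs(profile$dose[sel] - m)) / m
  } else {
    NA_real_
  }
  tibble(
    d50_mm = d50_distal(profile),
    proximal90_mm = b$proximal90_mm,
    distal90_mm = b$distal90_mm,
    extent_mm = b$extent_mm,
    flatness_pct = flat
  )
}
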