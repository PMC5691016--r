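#' Lineal energy samples from an event set
#'
#' Converts single-event energy depositions to lineal energy
#' `y = energy / mean chord length` in keV/um, with the mean chord fixed at
#' the slice thickness (0.02 mm = 20 um). One `y` per event.
#'
#' @param events An [sample_events()] result.
#' @return A `lineal_energy_dist` tibble with column `y_keV_um`; the slice
#'   depth and event count are carried as attributes. Fewer than 100 events
#'   attaches a warning attribute (distal slices are naturally event-poor);
#'   an empty event set is an error.
#' @export
#' @examples
#' sp <- beam_spec("127MeV", 99.5)
#' ev <- sample_events(sp, slice_spec(30), n_primaries = 1000, seed = 1)
#' y_dose_mean(lineal_energy(ev))
lineal_energy <- function(events) {
  stopifnot(inherits(events, "event_set"))
  slice <- attr(events, "slice")
  if (nrow(events) == 0) {
    abort("Event set is empty (slice beyond all fluence); no lineal energy distribution.")
  }
  if (slice$mean_chord <= 0) abort("Slice mean chord must be positive.")
  chord_um <- slice$mean_chord * 1000
  out <- tibble(y_keV_um = events$energy_keV / chord_um)
  class(out) <- c("lineal_energy_dist", class(out))
  attr(out, "depth") <- slice$depth
  attr(out, "n_events") <- nrow(out)
  if (nrow(out) < 100) {
    attr(out, "low_events_warning") <-
      sprintf("Only %d events; moments will be noisy.", nrow(out))
    warn(attr(out, "low_events_warning"))
  }
  out
}

y_samples <- function(dist) {
  if (inherits(dist, "lineal_energy_dist") || is.data.frame(dist)) {
    y <- dist[["y_keV_um"]] %||% dist[[1]]
  } else {
    y <- as.numeric(dist)
  }
  if (length(y) < 1) abort("Need at least one lineal energy sample.")
  if (any(y <= 0)) abort("Lineal energy samples must be positive.")
  y
}

#' Frequency-weighted mean lineal energy
#'
#' First moment of the empirical single-event lineal energy distribution:
#' the sample analog of the integral of `y f1(y)`.
#'
#' @param dist A [lineal_energy_dist][lineal_energy()] or numeric vector of
#'   `y` samples in keV/um.
#' @param weights Optional non-negative event weights (default equal).
#' @return Frequency-mean lineal energy in keV/um.
#' @export
y_frequency_mean <- function(dist, weights = NULL) {
  y <- y_samples(dist)
  if (is.null(weights)) return(mean(y))
  stopifnot(length(weights) == length(y), all(weights >= 0), sum(weights) > 0)
  sum(weights * y) / sum(weights)
}

#' Dose-weighted mean lineal energy
#'
#' Ratio of the second to the first moment of the empirical single-event
#' distribution: the sample analog of `(1/yF) * integral of y^2 f1(y)`.
#' Always at least the frequency mean (Cauchy-Schwarz), with equality only
#' when all samples coincide.
#'
#' @inheritParams y_frequency_mean
#' @return Dose-mean lineal energy in keV/um.
#' @export
y_dose_mean <- function(dist, weights = NULL) {
  y <- y_samples(dist)
  if (is.null(weights)) return(mean(y^2) / mean(y))
  stopifnot(length(weights) == length(y), all(weights >= 0), sum(weights) > 0)
  sum(weights * y^2) / sum(weights * y)
}

#' Dose-mean lineal energy versus depth
#'
#' Samples one scoring slice per requested depth, reduces each to its
#' frequency- and dose-weighted mean lineal energy, and pairs the result
#' with the beam's relative depth-dose curve for downstream ratio analysis.
#' Per-depth seeds are derived deterministically from `seed`.
#'
#' @param spec A [beam_spec()].
#' @param depths Depths in mm.
#' @param n_primaries Primaries per slice (default 1e4).
#' @param seed Integer seed.
#' @param ... Passed to [sample_events()].
#' @return A tibble with `depth_mm`, `n_events`, `yF_keV_um`, `yD_keV_um`,
#'   `relative_dose`.
#' @export
yd_vs_depth <- function(spec, depths, n_primaries = 1e4, seed, ...) {
  stopifnot(inherits(spec, "beam_spec"))
  if (missing(seed)) abort("`seed` must be supplied explicitly.")
  depth_curve <- if (spec$modulation > 0) sobp_synthesize(spec)$profile else pristine_bragg(spec)
  rows <- purrr::imap(depths, function(z, i) {
    ev <- sample_events(spec, slice_spec(z), n_primaries,
                        seed = as.integer(seed) + i, ...)
    if (nrow(ev) == 0) {
      return(tibble(depth_mm = z, n_events = 0L,
                    yF_keV_um = NA_real_, yD_keV_um = NA_real_))
    }
    dist <- suppressWarnings(lineal_energy(ev))
    tibble(depth_mm = z, n_events = nrow(ev),
           yF_keV_um = y_frequency_mean(dist),
           yD_keV_um = y_dose_mean(dist))
  })
  out <- dplyr::bind_rows(rows)
  out$relative_dose <- approx(depth_curve$position_mm, depth_curve$dose,
                              xout = out$depth_mm, rule = 2)$y
  class(out) <- c("microdose_curve", class(out))
  out
}
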