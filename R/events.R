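#' Microdosimetric scoring-slice geometry
#'
#' One transverse scoring slice: 20 x 20 voxels of 0.05 x 0.05 mm transverse
#' extent and 0.02 mm thickness along the beam, centered on the beam axis.
#' The mean chord length equals the slice thickness (0.02 mm = 20 um), so the
#' 400 voxels collectively match the sensitive-volume cross-section and
#' thickness of the diode.
#'
#' @param depth Slice depth in mm water-equivalent depth.
#' @param thickness Voxel thickness along the beam in mm (default 0.02).
#' @param transverse_voxel Transverse voxel side in mm (default 0.05).
#' @param extent Voxels per transverse side (default 20).
#' @return A `slice_spec` object.
#' @export
slice_spec <- function(depth, thickness = 0.02, transverse_voxel = 0.05, extent = 20L) {
  if (depth < 0) abort("`depth` must be >= 0.")
  if (thickness <= 0 || transverse_voxel <= 0 || extent < 1) {
    abort("Slice dimensions must be positive.")
  }
  structure(
    list(depth = depth, thickness = thickness,
         transverse_voxel = transverse_voxel, extent = as.integer(extent),
         n_voxels = as.integer(extent)^2,
         mean_chord = thickness),
    class = "slice_spec")
}

# depth-dependent stand-ins used by the event sampler -----------------------

# primary fluence relative to entrance: linear nuclear-removal ramp down to
# `fluence_end_fraction` at the peak, times the straggling survival sigmoid
fluence_factor <- function(spec, z) {
  cal <- bragg_calibration(spec$pristine_d50, spec$falloff_8020)
  ramp <- 1 - (1 - spec$fluence_end_fraction) * pmin(z, spec$pristine_d50) / spec$pristine_d50
  surv <- pnorm((spec$pristine_d50 - z) / cal$sigma) / pnorm(spec$pristine_d50 / cal$sigma)
  ramp * surv
}

# mean lineal energy (keV/um) of the configured stand-in LET curve: rises as
# residual range shrinks, capped within ~1 mm of the end of range
lineal_mean <- function(spec, z, entrance_lineal) {
  cal <- bragg_calibration(spec$pristine_d50, spec$falloff_8020)
  res <- pmax(cal$R0 - z, 1)
  entrance_lineal * (cal$R0 / res)^0.435
}

# heavy-tail mixture weight: 2% at entrance rising smoothly to 15% beyond the
# pristine distal-90% depth
tail_weight <- function(spec, z, w_entrance = 0.02, w_distal = 0.15) {
  cal <- bragg_calibration(spec$pristine_d50, spec$falloff_8020)
  zd90 <- curve_crossing(cal$curve$z, cal$curve$dose, 0.9, distal = TRUE)
  w_entrance + (w_distal - w_entrance) * pnorm((z - zd90) / 2)
}

#' Sample single-event energy depositions in a scoring slice
#'
#' Per-voxel event counts are Poisson with rate
#' `n_primaries * F(z) / n_voxels`, where the relative fluence `F(z)` falls
#' linearly to `fluence_end_fraction` at the peak (nuclear removal) and then
#' through the straggling sigmoid at the end of range. Event energies are a
#' two-component mixture: a Gamma-distributed primary component and an
#' exponential heavy tail (mean `tail_mean_ratio` times the primary mean)
#' whose weight rises from 2% at entrance to 15% beyond the distal-90% depth.
#' The component means are scaled so the overall mean of `energy / chord`
#' equals the configured depth-dependent mean lineal energy exactly.
#'
#' @param spec A [beam_spec()].
#' @param slice A [slice_spec()].
#' @param n_primaries Number of primaries aimed at the slice (>= 1).
#' @param seed Integer seed; required, all randomness is local to the call.
#' @param entrance_lineal Mean lineal energy at the surface, keV/um.
#' @param primary_shape Gamma shape of the primary component; `Inf` gives
#'   deterministic primary energies (no straggling spread).
#' @param tail_mean_ratio Mean of the exponential tail relative to the
#'   primary mean (default 10).
#' @param tail_weights Tail mixture weights `c(entrance, distal)`; set to
#'   `c(0, 0)` to disable the tail.
#' @param depth_profile `"bragg"` (mean lineal energy rises with depth) or
#'   `"constant"` (toy generator, flat in depth).
#' @return An `event_set`: tibble with `ix`, `iy` (0-based voxel indices) and
#'   `energy_keV`, with the slice, seed and sampling parameters as
#'   attributes. A slice beyond all fluence yields an empty, flagged set.
#' @export
sample_events <- function(spec, slice, n_primaries, seed,
                          entrance_lineal = 0.75,
                          primary_shape = 5,
                          tail_mean_ratio = 10,
                          tail_weights = c(0.02, 0.15),
                          depth_profile = c("bragg", "constant")) {
  stopifnot(inherits(spec, "beam_spec"), inherits(slice, "slice_spec"))
  depth_profile <- match.arg(depth_profile)
  if (missing(seed) || is.null(seed)) abort("`seed` must be supplied explicitly.")
  if (n_primaries < 1) abort("`n_primaries` must be >= 1.")
  z <- slice$depth
  F <- fluence_factor(spec, z)
  empty <- F * n_primaries < 1e-3
  ev <- withr::with_seed(as.integer(seed), {
    if (empty) {
      tibble(ix = integer(), iy = integer(), energy_keV = numeric())
    } else {
      counts <- rpois(slice$n_voxels, n_primaries * F / slice$n_voxels)
      n <- sum(counts)
      vox <- rep.int(seq_len(slice$n_voxels) - 1L, counts)
      L <- if (depth_profile == "bragg") lineal_mean(spec, z, entrance_lineal) else entrance_lineal
      w <- if (depth_profile == "bragg") {
        tail_weight(spec, z, tail_weights[1], tail_weights[2])
      } else {
        tail_weights[1]
      }
      chord_um <- slice$mean_chord * 1000
      m_total <- L * chord_um                        # keV
      m_primary <- m_total / (1 + (tail_mean_ratio - 1) * w)
      is_tail <- stats::runif(n) < w
      e <- numeric(n)
      np <- sum(!is_tail)
      e[!is_tail] <- if (is.finite(primary_shape)) {
        rgamma(np, shape = primary_shape, scale = m_primary / primary_shape)
      } else {
        rep(m_primary, np)
      }
      e[is_tail] <- rexp(sum(is_tail), rate = 1 / (tail_mean_ratio * m_primary))
      e <- pmax(e, 1e-9)                             # events deposit energy
      tibble(ix = vox %% slice$extent, iy = vox %/% slice$extent, energy_keV = e)
    }
  })
  class(ev) <- c("event_set", class(ev))
  attr(ev, "slice") <- slice
  attr(ev, "seed") <- as.integer(seed)
  attr(ev, "n_primaries") <- n_primaries
  attr(ev, "fluence_factor") <- F
  attr(ev, "empty") <- empty
  ev
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set: %d events at %.1f mm depth (seed %d)%s>\n",
              nrow(x), attr(x, "slice")$depth, attr(x, "seed"),
              if (isTRUE(attr(x, "empty"))) ", EMPTY (beyond fluence)" else ""))
  NextMethod()
}
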