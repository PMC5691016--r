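#' Diode charge-readout model
#'
#' Stochastic charge response of the diode electrometer chain:
#' `charge = sensitivity * dose * (1 - decay_rate * accumulated) *
#' orientation_factor[edge_on] * LET_factor + offset`, with multiplicative
#' Gaussian noise on the dose-dependent term. There is no dose-rate term:
#' the modeled response is uniform with dose rate by construction. The
#' optional LET over-response factor `1 + let_slope * max(0, y - let_threshold)`
#' is disabled by default (the diode shows negligible LET dependence up to
#' the very distal SOBP); the toggle exists to reproduce distal ratio rises
#' in comparisons.
#'
#' @param sensitivity Charge per dose in nC/Gy (default 3.3).
#' @param offset Electrometer offset in pC (default 100).
#' @param decay_rate Fractional sensitivity loss per Gy accumulated
#'   (default 1e-4, i.e. 1% per 100 Gy); must be below 1e-3.
#' @param orientation_factor Edge-on response relative to axial, within
#'   `[0.97, 1.03]` (default 0.994).
#' @param let_threshold,let_slope LET over-response threshold (keV/um) and
#'   slope (per keV/um); `let_threshold = NULL` disables the term.
#' @param noise_sd Relative standard deviation of the multiplicative noise
#'   (default 0.005).
#' @return A `readout_model` object.
#' @export
readout_model <- function(sensitivity = 3.3, offset = 100,
                          decay_rate = 1e-4, orientation_factor = 0.994,
                          let_threshold = NULL, let_slope = 0,
                          noise_sd = 0.005) {
  if (sensitivity <= 0) abort("`sensitivity` must be positive.")
  if (decay_rate < 0 || decay_rate >= 1e-3) {
    abort("`decay_rate` must be in [0, 1e-3) per Gy.")
  }
  if (orientation_factor < 0.97 || orientation_factor > 1.03) {
    abort("`orientation_factor` must lie within [0.97, 1.03].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(sensitivity = sensitivity, offset = offset, decay_rate = decay_rate,
         orientation_factor = orientation_factor,
         let_threshold = let_threshold, let_slope = let_slope,
         noise_sd = noise_sd),
    class = "readout_model")
}

#' Simulate a charge readout
#'
#' @param dose_gy Delivered dose(s) in Gy (>= 0); vectorized.
#' @param det A [detector_spec()] (the orientation factor applies edge-on).
#' @param model A [readout_model()].
#' @param accumulated_gy Dose accumulated before this reading, Gy (>= 0).
#' @param dose_rate_cgy_s Dose rate in cGy/s; accepted and ignored (the
#'   response is uniform with dose rate).
#' @param lineal_energy Dose-mean lineal energy at the measurement point in
#'   keV/um, used only when the model's LET term is enabled.
#' @param seed Integer seed for the noise draw; required unless
#'   `noise = FALSE`.
#' @param noise Draw multiplicative noise? `FALSE` gives the deterministic
#'   mean response.
#' @return Charge(s) in pC.
#' @export
#' @examples
#' m <- readout_model()
#' readout_charge(0, detector_spec("diode"), m, noise = FALSE)  # the offset
readout_charge <- function(dose_gy, det, model, accumulated_gy = 0,
                           dose_rate_cgy_s = NULL, lineal_energy = NULL,
                           seed = NULL, noise = TRUE) {
  stopifnot(inherits(det, "detector_spec"), inherits(model, "readout_model"))
  if (any(dose_gy < 0)) abort("`dose_gy` must be >= 0.")
  if (any(accumulated_gy < 0)) abort("`accumulated_gy` must be >= 0.")
  sens_pc <- model$sensitivity * 1000  # nC/Gy -> pC/Gy
  signal <- sens_pc * dose_gy * (1 - model$decay_rate * accumulated_gy)
  if (det$orientation == "edge_on") signal <- signal * model$orientation_factor
  if (!is.null(model$let_threshold) && !is.null(lineal_energy)) {
    signal <- signal * (1 + model$let_slope * pmax(0, lineal_energy - model$let_threshold))
  }
  if (noise && model$noise_sd > 0) {
    if (is.null(seed)) abort("`seed` must be supplied for a noisy readout.")
    eps <- withr::with_seed(as.integer(seed),
                            rnorm(length(signal), 0, model$noise_sd))
    signal <- signal * (1 + eps)
  }
  signal + model$offset
}

# --- precursory-experiment designs -----------------------------------------
# Synthetic versions of the four diode characterization runs: dose linearity,
# dose-rate uniformity, sensitivity decay with accumulated dose, and
# axial/edge-on orientation comparison.

#' Nine-dose linearity design (0.6 to 23 Gy)
#' @return Numeric vector of nine doses in Gy, evenly spaced 0.6-23.
#' @export
linearity_doses <- function() seq(0.6, 23, length.out = 9)

#' Simulate the dose-linearity experiment
#'
#' Delivers the nine-dose design to the axial diode and records accumulated
#' charge per dose.
#'
#' @param model A [readout_model()].
#' @param doses Doses in Gy (default [linearity_doses()]).
#' @param seed Integer seed.
#' @param det Detector (default axial diode).
#' @return Tibble with `dose_Gy`, `charge_pC`.
#' @export
simulate_linearity <- function(model, doses = linearity_doses(), seed,
                               det = detector_spec("diode")) {
  if (missing(seed)) abort("`seed` must be supplied explicitly.")
  tibble(
    dose_Gy = doses,
    charge_pC = readout_charge(doses, det, model, seed = seed)
  )
}

#' Simulate the sensitivity-decay experiment
#'
#' Baseline probe set, then `n_sets - 1` further probe sets each preceded by
#' a large accumulation increment (56 Gy). Probe doses themselves accrue to
#' the accumulated total. Set responses are normalized to the baseline set
#' mean.
#'
#' @param model A [readout_model()].
#' @param probe_dose Probe dose in Gy (default 2).
#' @param probes_per_set Probes per set (default 3).
#' @param n_sets Total probe sets including baseline (default 4).
#' @param increment Accumulation before each post-baseline set, Gy (default 56).
#' @param seed Integer seed.
#' @param det Detector (default axial diode).
#' @return Tibble with `set`, `accumulated_Gy` (set mean), `response`
#'   (normalized set-mean charge above offset).
#' @export
simulate_decay_study <- function(model, probe_dose = 2, probes_per_set = 3,
                                 n_sets = 4, increment = 56, seed,
                                 det = detector_spec("diode")) {
  if (missing(seed)) abort("`seed` must be supplied explicitly.")
  acc <- 0
  rows <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    if (s > 1) acc <- acc + increment
    probe_acc <- acc + (seq_len(probes_per_set) - 1) * probe_dose
    charge <- readout_charge(rep(probe_dose, probes_per_set), det, model,
                             accumulated_gy = probe_acc,
                             seed = as.integer(seed) + s)
    acc <- acc + probes_per_set * probe_dose
    rows[[s]] <- tibble(set = s, accumulated_Gy = mean(probe_acc),
                        mean_charge_pC = mean(charge - model$offset))
  }
  out <- dplyr::bind_rows(rows)
  out$response <- out$mean_charge_pC / out$mean_charge_pC[1]
  out[, c("set", "accumulated_Gy", "response")]
}

#' Simulate the orientation-comparison experiment
#'
#' Four replicates of a fixed dose in each orientation; records charge and
#' monitor units (1 MU per cGy here, so charge/MU tracks response).
#'
#' @param model A [readout_model()].
#' @param dose_gy Replicate dose in Gy (default 1.7, i.e. 170 cGy).
#' @param replicates Replicates per orientation (default 4).
#' @param seed Integer seed.
#' @return Tibble with `orientation`, `replicate`, `charge_pC`, `mu`.
#' @export
simulate_orientation_study <- function(model, dose_gy = 1.7, replicates = 4, seed) {
  if (missing(seed)) abort("`seed` must be supplied explicitly.")
  mu <- dose_gy * 100
  rows <- purrr::imap(c(axial = "axial", edge_on = "edge_on"), function(orient, nm) {
    det <- detector_spec("diode", orientation = orient)
    charge <- readout_charge(rep(dose_gy, replicates), det, model,
                             seed = as.integer(seed) + match(nm, c("axial", "edge_on")))
    tibble(orientation = nm, replicate = seq_len(replicates),
           charge_pC = charge, mu = mu)
  })
  dplyr::bind_rows(rows)
}

#' Simulate the dose-rate uniformity experiment
#'
#' A fixed dose delivered at each of the requested dose rates (default 14
#' rates spanning 0.7-2.3 cGy/s); the model has no dose-rate term, so any
#' apparent trend is noise.
#'
#' @param model A [readout_model()].
#' @param rates_cgy_s Dose rates in cGy/s.
#' @param dose_gy Dose per delivery in Gy (default 2).
#' @param seed Integer seed.
#' @return Tibble with `dose_rate_cgy_s`, `response` (charge above offset per
#'   MU, normalized to the series maximum).
#' @export
simulate_dose_rate_study <- function(model,
                                     rates_cgy_s = seq(0.7, 2.3, length.out = 14),
                                     dose_gy = 2, seed) {
  if (missing(seed)) abort("`seed` must be supplied explicitly.")
  det <- detector_spec("diode")
  charge <- readout_charge(rep(dose_gy, length(rates_cgy_s)), det, model,
                           dose_rate_cgy_s = rates_cgy_s, seed = seed)
  resp <- (charge - model$offset) / (dose_gy * 100)
  tibble(dose_rate_cgy_s = rates_cgy_s, response = resp / max(resp))
}
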