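#' Default acquisition noise
#'
#' Multiplicative noise for PC-MRI-like flow waveforms (velocity-encoding
#' errors scale with the signal) and additive noise for catheter-like
#' pressure waveforms (scaled by the local pulse pressure).
#'
#' @param flow_sd_frac standard deviation of the multiplicative flow
#'   noise, as a fraction of the signal.
#' @param pressure_sd_frac standard deviation of the additive pressure
#'   noise, as a fraction of the face pulse pressure.
#' @return a named list.
#' @export
default_noise_spec <- function(flow_sd_frac = 0.03,
                               pressure_sd_frac = 0.02) {
  stopifnot(flow_sd_frac >= 0, pressure_sd_frac >= 0)
  list(flow_sd_frac = flow_sd_frac, pressure_sd_frac = pressure_sd_frac)
}

#' Generate a synthetic clinical dataset
#'
#' Emulates the clinical acquisitions from a known ground-truth model:
#' cardiac-gated PC-MRI-like flow waveforms (40 phases per cycle) at the
#' SVC, IVC, LPA and RPA faces with multiplicative Gaussian noise, and
#' catheter-like pressure waveforms at the same faces plus the Fontan
#' pathway (mapped to the IVC-pathway node) on the fine simulation grid
#' with additive Gaussian noise. Patient descriptors (BSA, cycle length,
#' end-diastolic/systolic pressure-volume pairs) are derived from the
#' ground truth, and the full ground-truth parameter record is attached as
#' provenance.
#'
#' @param truth a `network_model`; the ground truth.
#' @param noise_spec a [default_noise_spec()] list.
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-exactly.
#' @param bsa body surface area, m^2.
#' @param n_phases number of flow phases per cycle.
#' @param sim optional precomputed `simulation_result` of `truth` (to
#'   avoid re-simulating when generating many noise realisations).
#' @return an object of class `clinical_dataset`: `flows` (per-face list
#'   of `time`/`Q`, 40 phases), `pressures` (per-face list of `time`/`P`),
#'   `patient`, `noise_spec`, `provenance`.
#' @export
generate_dataset <- function(truth = default_network(),
                             noise_spec = default_noise_spec(),
                             seed = 42, bsa = 0.51, n_phases = 40,
                             sim = NULL) {
  stopifnot(inherits(truth, "network_model"))
  if (is.null(sim)) sim <- run_to_periodicity(truth)
  set.seed(seed)
  flow_faces <- c("SVC", "IVC", "LPA", "RPA")
  flows <- lapply(flow_faces, function(f) {
    rs <- resample_phases(sim$time, sim$flows[, f], n_phases)
    noisy <- rs$x * (1 + stats::rnorm(n_phases, 0,
                                      noise_spec$flow_sd_frac))
    list(time = rs$time, Q = noisy)
  })
  names(flows) <- flow_faces
  press_faces <- c("SVC", "IVC", "LPA", "RPA")
  pressures <- lapply(press_faces, function(f) {
    P <- sim$pressures[, f]
    sd <- noise_spec$pressure_sd_frac * (max(P) - min(P))
    list(time = sim$time, P = P + stats::rnorm(length(P), 0, sd))
  })
  names(pressures) <- press_faces
  pressures$FONTAN <- pressures$IVC
  V <- sim$volume
  Prv <- sim$pressures[, "RV"]
  i_ed <- which.max(V)
  i_es <- which.min(V)
  patient <- list(BSA = bsa, T = truth$cycle_period,
                  EDV = V[i_ed], ESV = V[i_es],
                  EDP = Prv[i_ed], ESP = max(Prv))
  structure(list(flows = flows, pressures = pressures, patient = patient,
                 noise_spec = c(noise_spec, seed = seed),
                 provenance = list(truth = truth, seed = seed)),
            class = "clinical_dataset")
}

# Close a periodic phase grid by appending the wrapped first sample.
close_cycle <- function(time, x, T) {
  list(time = c(time, time[1] + T), x = c(x, x[1]))
}

#' Derive calibration targets from a clinical dataset
#'
#' Computes mean flows and retrograde volumes per beat from the 40-phase
#' flow waveforms (trapezoidal, with the cycle closed periodically) and
#' pressure summaries from the catheter-like waveforms, with the default
#' fit tolerances (2% flows, 7% retrograde volumes, 5% pressures).
#'
#' @param ds a `clinical_dataset`.
#' @return a [calibration_targets()] object.
#' @export
dataset_to_targets <- function(ds) {
  stopifnot(inherits(ds, "clinical_dataset"))
  faces <- c("SVC", "IVC", "LPA", "RPA")
  if (!all(faces %in% names(ds$flows)) ||
      !all(faces %in% names(ds$pressures))) {
    stop("dataset is missing one of the SVC/IVC/LPA/RPA faces")
  }
  T <- ds$patient$T
  mean_flows <- vapply(faces, function(f) {
    cc <- close_cycle(ds$flows[[f]]$time, ds$flows[[f]]$Q, T)
    trapz_mean(cc$time, cc$x)
  }, 0)
  retro <- vapply(c("IVC", "LPA", "RPA"), function(f) {
    cc <- close_cycle(ds$flows[[f]]$time, ds$flows[[f]]$Q, T)
    retrograde_volume(cc$time, cc$x, forward_sign = 1)
  }, 0)
  pres <- vapply(faces, function(f) {
    ps <- pressure_summary(ds$pressures[[f]]$time, ds$pressures[[f]]$P)
    ps[c("mean", "systolic", "diastolic")]
  }, numeric(3))
  calibration_targets(mean_flows, retro, pres)
}

#' The default synthetic clinical scenario
#'
#' The index scenario used throughout: the default ground-truth network
#' (tabulated heart/Windkessel parameters, calibrated junction surrogate)
#' observed through the default acquisition noise. It emulates a patient
#' with mean Fontan-pathway pressure near 15 mmHg, cycle length 0.8 s,
#' BSA 0.51 m^2 and hepatic venous reflux (nonzero retrograde IVC volume
#' per beat).
#'
#' @param seed RNG seed for the acquisition noise.
#' @param noise_spec a [default_noise_spec()] list.
#' @param sim optional precomputed truth simulation.
#' @return list with `truth` (`network_model`), `sim`
#'   (`simulation_result`), `dataset` (`clinical_dataset`) and `targets`
#'   ([calibration_targets()]).
#' @export
default_scenario <- function(seed = 42, noise_spec = default_noise_spec(),
                             sim = NULL) {
  truth <- default_network()
  if (is.null(sim)) sim <- run_to_periodicity(truth)
  ds <- generate_dataset(truth, noise_spec, seed = seed, sim = sim)
  list(truth = truth, sim = sim, dataset = ds,
       targets = dataset_to_targets(ds))
}
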