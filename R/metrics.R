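#' Pressure waveform summary
#'
#' Cycle mean (trapezoidal), systolic (maximum), diastolic (minimum) and
#' pulse (max - min) pressure of a periodic waveform.
#'
#' @param time time grid over one cycle, s.
#' @param P pressure samples, Pa.
#' @return named vector `c(mean =, systolic =, diastolic =, pulse =)`.
#' @export
pressure_summary <- function(time, P) {
  stopifnot(length(time) == length(P), length(P) >= 2)
  c(mean = trapz_mean(time, P), systolic = max(P), diastolic = min(P),
    pulse = max(P) - min(P))
}

#' Retrograde volume per beat
#'
#' Volume flowing against the forward direction of a face over one cycle:
#' the trapezoidal integral of the positive part of the reversed flow,
#' `max(-forward_sign * Q, 0)`.
#'
#' @param time time grid over one cycle, s.
#' @param Q flow samples, mm^3 s^-1.
#' @param forward_sign +1 if positive `Q` is the forward direction, -1
#'   otherwise.
#' @return retrograde volume, mm^3 per beat.
#' @export
retrograde_volume <- function(time, Q, forward_sign = 1) {
  stopifnot(length(time) == length(Q), forward_sign %in% c(-1, 1))
  trapz_integral(time, pmax(-forward_sign * Q, 0))
}

#' Face-flux energy accounting
#'
#' Energy fluxes across the model faces: E_in is the cycle average of
#' `sum_i Q_i (P_i + rho V_i^2 / 2)` over the inlet faces, E_out the same
#' over the outlets, with `V = Q / area` the face-mean velocity. The
#' instantaneous fluxes are formed pointwise and then cycle-averaged.
#' E_diss = E_in - E_out and E_eff = E_out / E_in.
#'
#' @param time time grid over one cycle, s.
#' @param inlets,outlets named lists of faces, each a list with elements
#'   `Q` (flow waveform, mm^3 s^-1), `P` (pressure waveform, Pa) and
#'   `area` (face area, mm^2).
#' @param rho blood density, g mm^-3.
#' @return list with `E_in`, `E_out`, `E_diss`, `E_eff`
#'   (fluxes in g mm^2 s^-3).
#' @export
energy_fluxes <- function(time, inlets, outlets, rho = 0.00106) {
  flux <- function(face) {
    stopifnot(all(c("Q", "P", "area") %in% names(face)))
    if (face$area <= 0 && any(face$Q != 0)) {
      stop("zero face area with nonzero flow")
    }
    v <- face$Q / face$area
    trapz_mean(time, face$Q * (face$P + 0.5 * rho * v^2))
  }
  E_in <- sum(vapply(inlets, flux, 0))
  E_out <- sum(vapply(outlets, flux, 0))
  list(E_in = E_in, E_out = E_out, E_diss = E_in - E_out,
       E_eff = E_out / E_in)
}

#' Non-dimensional energy dissipation
#'
#' Normalises a dissipated energy flux by `eps0 = rho * Q_ref^3 / BSA^2`
#' (BSA converted internally from m^2 to mm^2). `Q_ref` is taken as the
#' cycle-averaged total inlet flow.
#'
#' @param E_diss dissipated energy flux, g mm^2 s^-3.
#' @param rho blood density, g mm^-3.
#' @param Q_ref reference flow, mm^3 s^-1.
#' @param BSA body surface area, m^2.
#' @return list with `e_diss` (dimensionless) and `eps0` (g mm^2 s^-3).
#' @export
nondimensional_dissipation <- function(E_diss, rho, Q_ref, BSA) {
  if (Q_ref <= 0) stop("Q_ref must be positive")
  if (BSA <= 0) stop("BSA must be positive")
  eps0 <- rho * Q_ref^3 / (BSA * 1e6)^2
  list(e_diss = E_diss / eps0, eps0 = eps0)
}

#' Energy report for a simulated cycle
#'
#' Applies [energy_fluxes()] to the junction faces of a converged
#' simulation (inlets SVC/IVC, outlets LPA/RPA and the fenestration when
#' present) and attaches the non-dimensional dissipation.
#'
#' @param sim a `simulation_result`.
#' @param bsa body surface area, m^2.
#' @return an object of class `energy_report`.
#' @export
energy_report <- function(sim, bsa = 0.51) {
  stopifnot(inherits(sim, "simulation_result"))
  face <- function(f) list(Q = sim$flows[, f], P = sim$pressures[, f],
                           area = sim$face_areas[[tolower(f)]])
  inlets <- list(SVC = face("SVC"), IVC = face("IVC"))
  out_names <- c("LPA", "RPA")
  if (sim$model$junction$fenestration_present) {
    out_names <- c(out_names, "FEN")
  }
  outlets <- lapply(out_names, face)
  names(outlets) <- out_names
  ef <- energy_fluxes(sim$time, inlets, outlets, rho = sim$model$rho)
  Q_ref <- trapz_mean(sim$time, sim$flows[, "SVC"] + sim$flows[, "IVC"])
  nd <- nondimensional_dissipation(ef$E_diss, sim$model$rho, Q_ref, bsa)
  structure(c(ef, nd, list(Q_ref = Q_ref, BSA = bsa)),
            class = "energy_report")
}

#' Scalar hemodynamic summaries of a simulated cycle
#'
#' Mean flows, retrograde volumes per beat, pressure summaries, the
#' pulmonary flow split and the cardiac index; the quantities reported by
#' the pre/post-intervention comparison. Forward directions are into the
#' junction at the caval faces and out of it at the pulmonary and
#' fenestration faces.
#'
#' @param sim a `simulation_result`.
#' @param bsa body surface area, m^2.
#' @param n_phases if non-`NULL`, flow-derived summaries (mean flows and
#'   retrograde volumes at the acquisition faces) are computed from the
#'   waveforms resampled to this many phases per cycle, emulating the
#'   cardiac-gated acquisition; used by the calibration stage so simulated
#'   summaries and clinical targets share the same observation operator.
#' @return an object of class `metrics_report`: list with `mean_flows`
#'   (mm^3 s^-1), `retrograde_volumes` (mm^3 per beat), `pressures`
#'   (matrix of mean/systolic/diastolic/pulse, Pa), `flow_split_pct`
#'   (LPA/RPA, excluding fenestration flow), `cardiac_index`
#'   (L min^-1 m^-2) and `bsa`.
#' @export
metrics_report <- function(sim, bsa = 0.51, n_phases = NULL) {
  stopifnot(inherits(sim, "simulation_result"))
  t <- sim$time
  T <- t[length(t)] - t[1]
  face_wave <- function(f) {
    if (is.null(n_phases) || !(f %in% c("SVC", "IVC", "LPA", "RPA"))) {
      list(time = t, x = sim$flows[, f])
    } else {
      rs <- resample_phases(t, sim$flows[, f], n_phases)
      close_cycle(rs$time, rs$x, T)
    }
  }
  faces <- c("SVC", "IVC", "LPA", "RPA", "FEN", "AV")
  mean_flows <- vapply(faces, function(f) {
    w <- face_wave(f)
    trapz_mean(w$time, w$x)
  }, 0)
  retro <- vapply(c("SVC", "IVC", "LPA", "RPA"), function(f) {
    w <- face_wave(f)
    retrograde_volume(w$time, w$x, forward_sign = 1)
  }, 0)
  pfaces <- c("SVC", "IVC", "LPA", "RPA")
  pres <- vapply(pfaces, function(f) pressure_summary(t, sim$pressures[, f]),
                 numeric(4))
  qp <- mean_flows[c("LPA", "RPA")]
  split <- 100 * qp / sum(qp)
  structure(list(mean_flows = mean_flows,
                 retrograde_volumes = retro,
                 pressures = pres,
                 flow_split_pct = split,
                 cardiac_index = cardiac_index(mean_flows[["AV"]], bsa),
                 bsa = bsa),
            class = "metrics_report")
}

#' Flatten a metrics/energy report to named scalars
#'
#' @param metrics a `metrics_report`.
#' @param energy optional `energy_report`.
#' @return named numeric vector.
#' @export
report_scalars <- function(metrics, energy = NULL) {
  out <- c(stats::setNames(metrics$mean_flows,
                           paste0("mean_flow_", names(metrics$mean_flows))),
           stats::setNames(metrics$retrograde_volumes,
                           paste0("retro_vol_",
                                  names(metrics$retrograde_volumes))))
  for (f in colnames(metrics$pressures)) {
    out <- c(out, stats::setNames(metrics$pressures[, f],
                                  paste0("P_", f, "_",
                                         rownames(metrics$pressures))))
  }
  out <- c(out,
           flow_split_LPA = unname(metrics$flow_split_pct[["LPA"]]),
           flow_split_RPA = unname(metrics$flow_split_pct[["RPA"]]),
           cardiac_index = metrics$cardiac_index)
  if (!is.null(energy)) {
    out <- c(out, E_in = energy$E_in, E_out = energy$E_out,
             E_diss = energy$E_diss, E_eff = energy$E_eff,
             e_diss = energy$e_diss)
  }
  out
}

#' Pre- versus post-intervention comparison
#'
#' Percent change `100 * (post - pre) / pre` for every scalar shared by
#' the two reports. Metrics whose pre value is zero are reported as `NA`
#' (undefined change). A logical flag notes whether the revision dissipates
#' less energy (post/pre dissipation below one).
#'
#' @param pre,post named scalar vectors as from [report_scalars()].
#' @return a data frame with columns `metric`, `pre`, `post`,
#'   `pct_change`; attribute `more_efficient` holds the dissipation flag
#'   when both reports carry `E_diss`.
#' @export
compare_models <- function(pre, post) {
  shared <- intersect(names(pre), names(post))
  pv <- pre[shared]
  qv <- post[shared]
  pct <- ifelse(pv == 0, NA_real_, 100 * (qv - pv) / pv)
  out <- data.frame(metric = shared, pre = unname(pv), post = unname(qv),
                    pct_change = unname(pct), row.names = NULL)
  if ("E_diss" %in% shared && pre[["E_diss"]] != 0) {
    attr(out, "more_efficient") <- post[["E_diss"]] / pre[["E_diss"]] < 1
  }
  out
}
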