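#' Integrate the circulation to cycle-to-cycle periodicity
#'
#' Integrates the assembled network cycle by cycle with an adaptive stiff
#' solver (lsoda, relative tolerance 1e-6, absolute 1e-8, maximum step
#' `cycle_period / 400`) until, at every monitored face, the cycle means of
#' both pressure and flow change by less than `tol` (relative) between
#' consecutive cycles. Only the final converged cycle is returned, sampled
#' on a uniform 400-interval grid.
#'
#' @param model a `network_model`.
#' @param dt_max maximum solver step, s; default `cycle_period / 400`.
#' @param tol relative cycle-to-cycle convergence tolerance.
#' @param max_cycles maximum number of cycles to integrate.
#' @param y0 optional initial state (layout of [assemble_state_space()]).
#' @param n_grid number of output intervals per cycle.
#' @param freeze_elastance,force_valves_open diagnostic switches passed to
#'   [assemble_state_space()].
#' @return an object of class `simulation_result`: list with `time`
#'   (s, one cycle), `flows` (matrix, columns SVC/IVC/LPA/RPA/FEN/AV/TV,
#'   mm^3 s^-1), `pressures` (matrix, columns SVC/IVC/CONF/LPA/RPA/FEN/
#'   RV/AR, Pa), `volume` (ventricular volume, mm^3), `zeta`,
#'   `cycles_to_convergence`, `converged`, and the `model`.
#' @export
run_to_periodicity <- function(model, dt_max = NULL, tol = 1e-4,
                               max_cycles = 60, y0 = NULL, n_grid = 400,
                               freeze_elastance = FALSE,
                               force_valves_open = FALSE) {
  stopifnot(inherits(model, "network_model"), tol > 0, max_cycles >= 1)
  sys <- assemble_state_space(model, freeze_elastance = freeze_elastance,
                              force_valves_open = force_valves_open)
  T <- model$cycle_period
  if (is.null(dt_max)) dt_max <- T / 400
  times <- seq(0, T, length.out = n_grid + 1)
  y <- if (is.null(y0)) sys$y0 else {
    stopifnot(length(y0) == sys$n_states)
    y0
  }
  prev_summary <- NULL
  converged <- FALSE
  cycles <- 0L
  sol <- NULL
  last_change <- NA_real_
  for (cyc in seq_len(max_cycles)) {
    sol <- deSolve::ode(y = y, times = times, func = "circ_derivs",
                        parms = sys$parms, dllname = "fontanlpm",
                        initfunc = "circ_init", nout = sys$nout,
                        outnames = sys$outnames, method = "lsoda",
                        rtol = 1e-6, atol = 1e-8, hmax = dt_max,
                        maxsteps = 50000)
    cycles <- cyc
    y <- sol[nrow(sol), 1 + seq_len(sys$n_states)]
    if (any(sol[, "V_RV"] <= 0)) {
      stop("physiological failure: ventricular volume became non-positive")
    }
    summ <- cycle_summary_from_solution(sol, sys)
    if (!is.null(prev_summary)) {
      denom <- pmax(abs(summ), 1e-8 * max(abs(summ)))
      last_change <- max(abs(summ - prev_summary) / denom)
      if (last_change <= tol) {
        converged <- TRUE
        break
      }
    }
    prev_summary <- summ
  }
  if (!converged) {
    stop("no cycle-to-cycle periodicity after ", max_cycles,
         " cycles (last max relative change ", signif(last_change, 3),
         "); increase max_cycles or loosen tol")
  }
  build_simulation_result(sol, sys, model, cycles, y)
}

# Cycle means of the monitored face flows and pressures (trapezoid on the
# uniform output grid).
cycle_summary_from_solution <- function(sol, sys) {
  cols <- c("Q_svc_face", "Q_ivc_face", "q_lpa", "q_rpa", "q_AV",
            "P_svc", "P_ivc", "P_lpa_face", "P_rpa_face", "P_AR")
  if (sys$fen_present) cols <- c(cols, "Q_fen_face", "P_fen_face")
  vapply(cols, function(cn) trapz_mean(sol[, "time"], sol[, cn]), 0)
}

trapz_integral <- function(t, x) {
  n <- length(t)
  sum((x[-1] + x[-n]) * diff(t)) / 2
}

trapz_mean <- function(t, x) trapz_integral(t, x) / (t[length(t)] - t[1])

build_simulation_result <- function(sol, sys, model, cycles, final_state) {
  fen <- sys$fen_present
  zero <- rep(0, nrow(sol))
  flows <- cbind(SVC = sol[, "Q_svc_face"],
                 IVC = sol[, "Q_ivc_face"],
                 LPA = sol[, "q_lpa"],
                 RPA = sol[, "q_rpa"],
                 FEN = if (fen) sol[, "Q_fen_face"] else zero,
                 AV  = sol[, "q_AV"],
                 TV  = sol[, "q_TV_fwd"])
  pressures <- cbind(SVC = sol[, "P_svc"],
                     IVC = sol[, "P_ivc"],
                     CONF = sol[, "P_conf"],
                     LPA = sol[, "P_lpa_face"],
                     RPA = sol[, "P_rpa_face"],
                     FEN = if (fen) sol[, "P_fen_face"] else zero,
                     RV = sol[, "P_RV"],
                     AR = sol[, "P_AR"])
  structure(list(time = sol[, "time"],
                 flows = flows,
                 pressures = pressures,
                 volume = sol[, "V_RV"],
                 zeta = sol[, "zeta"],
                 elastance = sol[, "E"],
                 cycles_to_convergence = cycles,
                 converged = TRUE,
                 final_state = final_state,
                 face_areas = model$junction$face_areas,
                 model = model),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>: one converged cycle,",
      length(x$time) - 1, "intervals,",
      x$cycles_to_convergence, "cycles to periodicity\n")
  cat(sprintf("  mean IVC pressure: %.1f mmHg; mean aortic flow: %.0f mm^3/s\n",
              Pa_to_mmHg(trapz_mean(x$time, x$pressures[, "IVC"])),
              trapz_mean(x$time, x$flows[, "AV"])))
  invisible(x)
}

#' Resample a periodic waveform to a coarser phase grid
#'
#' Linear interpolation of a one-cycle waveform onto `n_phases` uniformly
#' spaced phases (the convention of cardiac-gated PC-MRI reconstructions:
#' phase k at time k*T/n, k = 0..n-1).
#'
#' @param time time grid of one cycle (first and last point one period
#'   apart).
#' @param x waveform samples on `time`.
#' @param n_phases number of output phases.
#' @return list with `time` and `x` of length `n_phases`.
#' @export
resample_phases <- function(time, x, n_phases = 40) {
  T <- time[length(time)] - time[1]
  tout <- time[1] + (seq_len(n_phases) - 1) * T / n_phases
  list(time = tout, x = stats::approx(time, x, xout = tout)$y)
}
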