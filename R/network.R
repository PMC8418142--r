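#' Open-loop circulation network model
#'
#' Assembles the heart, the five Windkessel beds and the Fontan-pathway
#' surrogate into the open-loop network: heart -> aortic root -> upper and
#' lower body Windkessels in series -> SVC/IVC inlets -> pathway surrogate
#' -> LPA/RPA Windkessel terminations, with an optional fenestration branch
#' draining the IVC-pathway node to a Windkessel referenced to atrial
#' pressure.
#'
#' @param heart a [heart_params()] object.
#' @param ubv,lbv upper/lower body vasculature [windkessel_params()].
#' @param lpa,rpa pulmonary [windkessel_params()] (distal reference 0 by
#'   default).
#' @param fen fenestration [windkessel_params()]; its distal reference is
#'   forced to the atrial pressure `heart$P_RA`.
#' @param junction a `junction_surrogate` from [build_pre_junction()] or
#'   [apply_endograft()].
#' @param rho blood density, g mm^-3.
#' @param mu dynamic viscosity, Pa s.
#' @return an object of class `network_model`.
#' @export
network_model <- function(heart = heart_params(),
                          ubv = windkessel_params(0.1047, 4.0000, 0.1684),
                          lbv = windkessel_params(0.1847, 0.9000, 0.0884),
                          lpa = windkessel_params(0.0040, 7.1974, 0.3995),
                          rpa = windkessel_params(0.0054, 9.3408, 0.2668),
                          fen = windkessel_params(0.2517, 1.3703, 1.4265),
                          junction = build_pre_junction(),
                          rho = 0.00106, mu = 0.004) {
  stopifnot(inherits(heart, "heart_params"),
            inherits(junction, "junction_surrogate"))
  for (wk in list(ubv, lbv, lpa, rpa, fen)) {
    stopifnot(inherits(wk, "windkessel_params"))
  }
  fen$P_distal <- heart$P_RA
  structure(list(heart = heart, ubv = ubv, lbv = lbv, lpa = lpa,
                 rpa = rpa, fen = fen, junction = junction,
                 cycle_period = heart$elastance$T, rho = rho, mu = mu),
            class = "network_model")
}

#' Default pre-intervention network
#'
#' The index scenario: tabulated heart and Windkessel parameters with the
#' default (calibrated) pathway surrogate. This is the ground-truth model
#' behind the default synthetic clinical scenario.
#'
#' @param pouch_loss_R pouch dissipation resistance, Pa s mm^-3 (see the
#'   methods vignette for how the default was fixed).
#' @return a `network_model`.
#' @export
default_network <- function(pouch_loss_R = default_pouch_loss_R()) {
  network_model(junction = build_pre_junction(pouch_loss_R = pouch_loss_R))
}

#' @rdname default_network
#' @export
default_pouch_loss_R <- function() 0.015

state_names_pre <- c("V_RV", "q_TV", "zeta", "q_AV", "P_AR", "P_C_ubv",
                     "P_C_lbv", "P_svc", "P_ivc", "P_conf", "q_svc",
                     "q_ivc", "q_lpa", "q_rpa", "P_C_lpa", "P_C_rpa",
                     "q_fen", "P_C_fen")
output_names <- c("P_RV", "E", "Q_svc_face", "Q_ivc_face", "P_lpa_face",
                  "P_rpa_face", "P_fen_face", "q_TV_fwd", "Q_fen_face")

#' Assemble the state-space system
#'
#' Packs a `network_model` into the flat parameter vector consumed by the
#' compiled right-hand side, together with the state layout and a default
#' initial condition. The state vector is
#' `[V_RV, q_TV, zeta, q_AV, P_AR, P_C_ubv, P_C_lbv, P_svc, P_ivc, P_conf,
#' q_svc, q_ivc, q_lpa, q_rpa, P_C_lpa, P_C_rpa (, q_fen, P_C_fen)]`;
#' the fenestration states are present only when the junction carries a
#' fenestration.
#'
#' @param model a `network_model`.
#' @param freeze_elastance logical; hold the elastance at its minimum
#'   (diagnostic mode used by the steady-state oracle tests).
#' @param force_valves_open logical; disable valve dynamics, holding the
#'   aortic valve fully open and the tricuspid diode conducting.
#' @return a list with elements `parms`, `state_names`, `y0`, `n_states`,
#'   `nout`, `outnames` and `fen_present`.
#' @export
assemble_state_space <- function(model, freeze_elastance = FALSE,
                                 force_valves_open = FALSE) {
  stopifnot(inherits(model, "network_model"))
  h <- model$heart
  el <- h$elastance
  vp <- h$valve
  jn <- model$junction
  if (abs(model$cycle_period - el$T) > 1e-12) {
    stop("assembly error: cycle period does not match elastance period")
  }
  wk_vec <- function(w) c(w$R_p, w$C, w$R_d, w$P_distal)
  segs <- jn$segments
  nodeC <- jn$node_compliances
  parms <- c(
    el$T, el$E_min, el$k, el$tau1, el$m1, el$tau2, el$m2, h$V_rest,
    h$P_RA, h$R_TV, h$I_TV, h$C_AR, h$I_AR,
    vp$A_ann, vp$p_open, vp$p_close, vp$K_vo, vp$K_vc, vp$M_rg, vp$M_st,
    vp$l_eff, vp$rho, if (isTRUE(vp$use_Ks)) vp$rho * vp$K_s else 0,
    wk_vec(model$ubv), wk_vec(model$lbv), wk_vec(model$lpa),
    wk_vec(model$rpa), wk_vec(model$fen),
    as.numeric(jn$fenestration_present),
    segs$svc$R, segs$svc$L,
    segs$ivc$R + jn$pouch_loss_R, segs$ivc$L,
    segs$lpa$R, segs$lpa$L,
    segs$rpa$R, segs$rpa$L,
    segs$fen$R, segs$fen$L,
    nodeC["svc"], nodeC["ivc"], nodeC["conf"],
    as.numeric(freeze_elastance), as.numeric(force_valves_open),
    100
  )
  parms <- unname(parms)
  if (length(parms) != 60) stop("assembly error: bad parameter packing")
  fen_present <- jn$fenestration_present
  n <- if (fen_present) 18L else 16L
  snames <- state_names_pre[seq_len(n)]
  # start near a plausible venous-congested operating point
  y0 <- c(V_RV = h$P_RA / el$E_min + h$V_rest, q_TV = 100, zeta = 0,
          q_AV = 0, P_AR = 3000, P_C_ubv = 2500, P_C_lbv = 2500,
          P_svc = 2000, P_ivc = 2000, P_conf = 1900, q_svc = 4000,
          q_ivc = 6000, q_lpa = 5000, q_rpa = 6000, P_C_lpa = 1800,
          P_C_rpa = 1800, q_fen = 500, P_C_fen = 1200)[seq_len(n)]
  list(parms = parms, state_names = snames, y0 = y0, n_states = n,
       nout = 9L, outnames = output_names, fen_present = fen_present)
}

#' Evaluate the network right-hand side once
#'
#' Direct call into the compiled derivative function; used by tests and
#' steady-state oracles.
#'
#' @param t time, s.
#' @param y state vector (layout of [assemble_state_space()]).
#' @param sys an assembled system from [assemble_state_space()].
#' @return list with `ydot` (state derivatives) and `out` (named
#'   auxiliary outputs).
#' @export
network_rhs <- function(t, y, sys) {
  res <- .Call("C_circ_rhs", as.numeric(t), as.numeric(y),
               as.numeric(sys$parms), PACKAGE = "fontanlpm")
  names(res$ydot) <- sys$state_names
  names(res$out) <- sys$outnames
  res
}
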