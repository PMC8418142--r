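#' Two-Hill elastance parameters
#'
#' Parameter block for the periodic time-varying elastance of the single
#' ventricle. The activation shape is the product of an ascending and a
#' descending Hill function; a scaling factor (computed on construction by
#' dense grid maximisation of the shape) guarantees that the elastance
#' ranges exactly over \[E_min, E_max\] each cycle.
#'
#' @param E_max maximum (end-systolic) elastance, Pa mm^-3.
#' @param E_min minimum (end-diastolic) elastance, Pa mm^-3.
#' @param T cycle period, s.
#' @param tau1_frac ascending time constant as a fraction of `T`.
#' @param m1 ascending Hill exponent (dimensionless).
#' @param tau2_frac descending time constant as a fraction of `T`.
#' @param m2 descending Hill exponent (dimensionless).
#' @param n_grid grid size used to locate the maximum of the unscaled
#'   activation shape.
#' @return an object of class `elastance_params`.
#' @export
elastance_params <- function(E_max = 0.875, E_min = 0.03, T = 0.8,
                             tau1_frac = 0.4944, m1 = 2.6,
                             tau2_frac = 0.5493, m2 = 18,
                             n_grid = 1e5) {
  stopifnot(is.finite(E_max), is.finite(E_min), E_max > E_min, E_min > 0,
            T > 0, tau1_frac > 0, tau1_frac < 1, tau2_frac > 0,
            tau2_frac < 1, m1 > 0, m2 > 0)
  p <- list(E_max = E_max, E_min = E_min, T = T,
            tau1 = tau1_frac * T, m1 = m1,
            tau2 = tau2_frac * T, m2 = m2)
  p$k <- elastance_scale_factor(p, n_grid = n_grid)
  structure(p, class = "elastance_params")
}

# Unscaled double-Hill activation shape on [0, T).
elastance_shape <- function(t, p) {
  g1 <- (t / p$tau1)^p$m1
  g2 <- (t / p$tau2)^p$m2
  (g1 / (1 + g1)) * (1 / (1 + g2))
}

# Scaling factor k = (E_max - E_min) / max(shape), max located on a dense
# uniform grid over one period.
elastance_scale_factor <- function(p, n_grid = 1e5) {
  tg <- seq(0, p$T, length.out = n_grid + 1)[-(n_grid + 1)]
  (p$E_max - p$E_min) / max(elastance_shape(tg, p))
}

#' Two-Hill time-varying elastance
#'
#' Evaluates the periodic ventricular elastance E(t) = k * g1/(1+g1) *
#' 1/(1+g2) + E_min, with g1 = (t/tau1)^m1 and g2 = (t/tau2)^m2. Time is
#' reduced modulo the cycle period; the scaling factor k stored in `p`
#' makes the cycle minimum equal E_min and the maximum equal E_max.
#'
#' @param t time, s (any finite value; reduced modulo the period).
#' @param p an [elastance_params()] object.
#' @return elastance in Pa mm^-3, same length as `t`.
#' @export
elastance_two_hill <- function(t, p) {
  stopifnot(inherits(p, "elastance_params"))
  if (any(!is.finite(t))) stop("`t` must be finite")
  tt <- t %% p$T
  p$k * elastance_shape(tt, p) + p$E_min
}

#' Elastance bounds from clinical pressure-volume pairs
#'
#' Minimum elastance is end-diastolic pressure over end-diastolic volume;
#' maximum elastance is end-systolic pressure over end-systolic volume.
#' Inputs are accepted in clinical units (mmHg, mL) and converted to the
#' internal g-mm-s system.
#'
#' @param edp end-diastolic pressure, mmHg.
#' @param edv end-diastolic volume, mL.
#' @param esp end-systolic pressure, mmHg.
#' @param esv end-systolic volume, mL.
#' @return named numeric vector `c(E_min =, E_max =)` in Pa mm^-3.
#' @export
compute_elastance_bounds <- function(edp, edv, esp, esv) {
  stopifnot(edp >= 0, esp >= 0)
  if (edv <= 0 || esv <= 0) stop("chamber volumes must be positive")
  c(E_min = mmHg_to_Pa(edp) / mL_to_mm3(edv),
    E_max = mmHg_to_Pa(esp) / mL_to_mm3(esv))
}

#' Dynamically controlled valve parameters
#'
#' Parameter block for the pressure-driven valve model: the opening state
#' zeta in \[0,1\] evolves at a rate set by the transvalvular pressure, and
#' the instantaneous pressure drop follows a quadratic (Bernoulli) law plus
#' blood inertance through the effective orifice
#' A_eff(zeta) = (M_st - M_rg) * A_ann * zeta + M_rg * A_ann.
#'
#' `K_s` is retained as an optional additional linear resistance term
#' (rho * K_s * q), disabled by default.
#'
#' @param A_ann annulus area, mm^2.
#' @param p_open opening pressure threshold, Pa.
#' @param p_close closing pressure threshold, Pa.
#' @param K_vo opening rate coefficient, Pa^-1 s^-1.
#' @param K_vc closing rate coefficient, Pa^-1 s^-1.
#' @param M_rg regurgitant (minimum) area fraction.
#' @param M_st maximal-opening area fraction.
#' @param l_eff effective length, mm.
#' @param rho blood density, g mm^-3.
#' @param K_s auxiliary resistance coefficient, s mm^-3 (inert unless
#'   `use_Ks = TRUE`).
#' @param use_Ks logical; include the linear `rho * K_s * q` term.
#' @return an object of class `valve_params`.
#' @export
valve_params <- function(A_ann = 60, p_open = 0, p_close = 1333,
                         K_vo = 0.2, K_vc = 0.2, M_rg = 0.5, M_st = 1.0,
                         l_eff = 15, rho = 0.00106, K_s = 1.5e-6,
                         use_Ks = FALSE) {
  stopifnot(A_ann > 0, K_vo > 0, K_vc > 0, M_rg >= 0, M_st <= 1,
            M_rg <= M_st, l_eff > 0, rho > 0)
  structure(list(A_ann = A_ann, p_open = p_open, p_close = p_close,
                 K_vo = K_vo, K_vc = K_vc, M_rg = M_rg, M_st = M_st,
                 l_eff = l_eff, rho = rho, K_s = K_s, use_Ks = use_Ks),
            class = "valve_params")
}

#' Valve opening-state rate
#'
#' Rate of change of the valve opening state zeta. The valve opens when the
#' transvalvular pressure exceeds `p_open` (rate proportional to the
#' remaining opening reserve 1 - zeta) and closes when it falls below
#' `-p_close` (rate proportional to zeta); in between the state is frozen.
#' The returned rate never drives zeta outside \[0, 1\].
#'
#' @param zeta opening state in \[0, 1\].
#' @param dp transvalvular pressure (upstream minus downstream), Pa.
#' @param p a [valve_params()] object.
#' @return dzeta/dt, s^-1.
#' @export
valve_state_rate <- function(zeta, dp, p) {
  stopifnot(inherits(p, "valve_params"))
  if (any(zeta < 0 | zeta > 1)) stop("`zeta` must lie in [0, 1]")
  rate <- numeric(length(zeta))
  opening <- dp > p$p_open
  closing <- dp < -p$p_close
  rate[opening] <- (1 - zeta[opening]) * p$K_vo * (dp[opening] - p$p_open)
  rate[closing] <- zeta[closing] * p$K_vc * (dp[closing] + p$p_close)
  rate
}

# Effective orifice area at opening state zeta.
valve_effective_area <- function(zeta, p) {
  (p$M_st - p$M_rg) * p$A_ann * zeta + p$M_rg * p$A_ann
}

#' Instantaneous valve pressure drop
#'
#' Quadratic-Bernoulli plus inertance law through the effective orifice:
#' dp = B q |q| + L_v dq/dt with B = rho / (2 A_eff^2) and
#' L_v = rho l_eff / A_eff. An optional linear `rho K_s q` resistance term
#' is added when the valve was built with `use_Ks = TRUE`.
#'
#' @param q flow through the valve, mm^3 s^-1.
#' @param dq_dt flow acceleration, mm^3 s^-2.
#' @param zeta opening state in \[0, 1\].
#' @param p a [valve_params()] object.
#' @return pressure drop, Pa.
#' @export
valve_pressure_drop <- function(q, dq_dt, zeta, p) {
  stopifnot(inherits(p, "valve_params"))
  if (any(zeta < 0 | zeta > 1)) stop("`zeta` must lie in [0, 1]")
  A_eff <- valve_effective_area(zeta, p)
  if (any(A_eff <= 0 & q != 0)) {
    stop("degenerate valve: zero effective area with nonzero flow")
  }
  B <- p$rho / (2 * A_eff^2)
  L_v <- p$rho * p$l_eff / A_eff
  dp <- B * q * abs(q) + L_v * dq_dt
  if (isTRUE(p$use_Ks)) dp <- dp + p$rho * p$K_s * q
  dp
}

#' Three-element Windkessel parameters
#'
#' Proximal resistance, compliance (shunted to the distal reference) and
#' distal resistance representing a downstream vascular bed.
#'
#' @param R_p proximal resistance, Pa s mm^-3.
#' @param C compliance, mm^3 Pa^-1.
#' @param R_d distal resistance, Pa s mm^-3.
#' @param P_distal distal reference pressure, Pa.
#' @return an object of class `windkessel_params`.
#' @export
windkessel_params <- function(R_p, C, R_d, P_distal = 0) {
  stopifnot(R_p > 0, C > 0, R_d > 0, P_distal >= 0)
  structure(list(R_p = R_p, C = C, R_d = R_d, P_distal = P_distal),
            class = "windkessel_params")
}

#' Steady-state Windkessel pressure
#'
#' Closed-form mean inlet pressure of a three-element Windkessel under
#' steady flow: P = q (R_p + R_d) + P_distal. Used for calibration seeding
#' and as an analytic cross-check of the dynamic model.
#'
#' @param q_mean mean flow, mm^3 s^-1.
#' @param p a [windkessel_params()] object.
#' @return inlet pressure, Pa.
#' @export
windkessel_mean_pressure <- function(q_mean, p) {
  stopifnot(inherits(p, "windkessel_params"), is.finite(q_mean))
  q_mean * (p$R_p + p$R_d) + p$P_distal
}

#' Reduce a compliant tube to lumped R, L, C
#'
#' Maps tube geometry and wall properties to zero-dimensional parameters:
#' Poiseuille resistance R = 8 mu l / (pi r^4), blood inertance
#' L = rho l / (pi r^2), and thin-walled-vessel compliance
#' C = 3 pi r^3 l / (2 E h).
#'
#' @param radius luminal radius, mm.
#' @param length segment length, mm.
#' @param wall_stiffness wall elastic modulus E, Pa.
#' @param wall_thickness wall thickness h, mm.
#' @param mu dynamic viscosity, Pa s.
#' @param rho blood density, g mm^-3.
#' @return named numeric vector `c(R =, L =, C =)`.
#' @export
tube_segment_reduce <- function(radius, length, wall_stiffness,
                                wall_thickness, mu = 0.004, rho = 0.00106) {
  vals <- c(radius, length, wall_stiffness, wall_thickness, mu, rho)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tube parameters must be positive and finite")
  }
  radius <- unname(radius); length <- unname(length)
  wall_stiffness <- unname(wall_stiffness)
  wall_thickness <- unname(wall_thickness)
  mu <- unname(mu); rho <- unname(rho)
  c(R = 8 * mu * length / (pi * radius^4),
    L = rho * length / (pi * radius^2),
    C = 3 * pi * radius^3 * length / (2 * wall_stiffness * wall_thickness))
}

#' Tube segment
#'
#' A named vascular segment with its geometry, wall properties and derived
#' lumped parameters.
#'
#' @param name segment identifier.
#' @param radius luminal radius, mm.
#' @param length segment length, mm.
#' @param wall_stiffness wall elastic modulus, Pa.
#' @param wall_thickness wall thickness, mm.
#' @param mu dynamic viscosity, Pa s.
#' @param rho blood density, g mm^-3.
#' @return an object of class `tube_segment` with fields `R`, `L`, `C` and
#'   `face_area` (mm^2).
#' @export
tube_segment <- function(name, radius, length, wall_stiffness = 1e6,
                         wall_thickness = 0.5, mu = 0.004, rho = 0.00106) {
  rlc <- tube_segment_reduce(radius, length, wall_stiffness, wall_thickness,
                             mu, rho)
  structure(list(name = name, radius = radius, length = length,
                 wall_stiffness = wall_stiffness,
                 wall_thickness = wall_thickness,
                 R = unname(rlc["R"]), L = unname(rlc["L"]),
                 C = unname(rlc["C"]),
                 face_area = pi * radius^2),
            class = "tube_segment")
}

#' Single-ventricle heart model parameters
#'
#' Combines the constant right-atrial pressure source, the tricuspid
#' diode-inductor branch, the aortic-root compliance and inertance, the
#' unstressed ventricular volume and the elastance and aortic-valve
#' parameter blocks.
#'
#' @param P_RA right-atrial pressure, Pa.
#' @param R_TV tricuspid resistance, Pa s mm^-3.
#' @param I_TV tricuspid inductance, Pa s^2 mm^-3.
#' @param C_AR aortic-root compliance, mm^3 Pa^-1.
#' @param I_AR aortic-root inertance, Pa s^2 mm^-3.
#' @param V_rest unstressed ventricular volume, mm^3.
#' @param elastance an [elastance_params()] object.
#' @param valve a [valve_params()] object for the aortic valve.
#' @return an object of class `heart_params`.
#' @export
heart_params <- function(P_RA = 629, R_TV = 1.1e-5, I_TV = 1.0e-5,
                         C_AR = 0.5, I_AR = 2.0e-6, V_rest = 0,
                         elastance = elastance_params(),
                         valve = valve_params()) {
  stopifnot(P_RA >= 0, R_TV > 0, I_TV > 0, C_AR > 0, I_AR > 0, V_rest >= 0,
            inherits(elastance, "elastance_params"),
            inherits(valve, "valve_params"))
  structure(list(P_RA = P_RA, R_TV = R_TV, I_TV = I_TV, C_AR = C_AR,
                 I_AR = I_AR, V_rest = V_rest, elastance = elastance,
                 valve = valve),
            class = "heart_params")
}
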