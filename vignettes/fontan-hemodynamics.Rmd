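---
title: "A lumped-parameter model of a fenestrated lateral-tunnel Fontan circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of a fenestrated lateral-tunnel Fontan circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontanlpm)
```

## The physiological problem

In a Fontan circulation the systemic venous return drains passively into
the pulmonary arteries: there is no subpulmonary ventricle, so the whole
circuit is driven by a single (here morphologically right) ventricle. The
scenario this package models is a young child with a lateral-tunnel
Fontan whose inferior pathway has become severely dilated: the pouch
hosts slow swirling flow, the pathway pressure is elevated (around
15 mmHg), and blood refluxes into the hepatic veins every beat. A
candidate endovascular revision — relining the pathway with a bifurcated
endograft (10 mm main body into the inferior vena cava, 8 mm limb into
the superior vena cava) and closing the fenestration to the right
atrium — can be rehearsed *in silico* before anyone commits a patient to
it.

The package implements that rehearsal at zero spatial dimensions: every
vessel compartment becomes a resistance (viscous loss), an inertance
(blood momentum) and a compliance (wall distension), and the heart
becomes a time-varying elastance. A 0D model cannot resolve swirling
flow or wall mechanics, but it can answer the system-level questions —
where do mean pressures, flow splits, reflux volumes and transmitted
energy move when the pathway is relined — in seconds on a desk machine.

## Model structure

The open-loop network is, in order:

1. **Right atrium**: a constant pressure source `P_RA` (629 Pa).
2. **Tricuspid valve**: an ideal diode in series with a resistance
   `R_TV` and an inductance `I_TV`.
3. **Ventricle**: `P_RV(t) = E(t) (V - V_rest)` with the two-Hill
   elastance

   `E(t) = k * g1/(1+g1) * 1/(1+g2) + E_min`,
   `g1 = (t/tau1)^m1`, `g2 = (t/tau2)^m2`,

   where the scale factor `k = (E_max - E_min) / max(shape)` is found by
   dense grid search (1e5 samples per period) so the elastance ranges
   exactly over `[E_min, E_max]`. `E_min = EDP/EDV = 0.03 Pa mm^-3` and
   `E_max = ESP/ESV = 0.875 Pa mm^-3` come from catheter pressure-volume
   pairs (7 mmHg / 31 mL and 105 mmHg / 16 mL).
4. **Aortic valve**: a pressure-driven opening state `zeta` in [0, 1]
   (opening rate `(1-zeta) K_vo (dp - p_open)` above `p_open`, closing
   rate `zeta K_vc (dp + p_close)` below `-p_close`, frozen in between)
   modulating an effective orifice
   `A_eff = (M_st - M_rg) A_ann zeta + M_rg A_ann`, with pressure drop
   `B q|q| + L_v dq/dt`, `B = rho/(2 A_eff^2)`,
   `L_v = rho l_eff / A_eff`. The tabulated `M_rg = 0.5` implies a large
   regurgitant orifice; it is used as printed (see *Limitations*).
5. **Aortic root**: compliance `C_AR` and inertance `I_AR` (lumped into
   the valve branch).
6. **Upper- and lower-body vascular beds**: three-element Windkessels in
   series within the loop — each bed's proximal resistance drains the
   aortic root into the bed compliance, and the distal resistance feeds
   the corresponding caval inlet of the Fontan pathway.
7. **Fontan-pathway surrogate**: R-L tube segments (SVC limb, dilated
   IVC limb, LPA and RPA limbs, fenestration neck) around three
   compliant nodes (SVC inlet, IVC pathway, confluence), reduced from
   geometry by Poiseuille resistance `8 mu l/(pi r^4)`, inertance
   `rho l/(pi r^2)` and thin-wall compliance `3 pi r^3 l/(2 E h)`.
8. **Outlets**: LPA and RPA Windkessels referenced to 0 Pa, and the
   fenestration Windkessel referenced to `P_RA` (it drains into the
   right atrium).

All quantities are in the g-mm-s system (pressure Pa, flow mm^3 s^-1,
volume mm^3); clinical units (mmHg, mL, L min^-1 m^-2) appear only at
the I/O layer. The heart, valve and Windkessel defaults are exactly the
tabulated calibrated values; a configuration written by
`write_model_config()` reproduces them digit for digit.

## Choices the data did not fix

Several constants have no measured or tabulated value and had to be set once:

* **Pathway geometry.** Radii and lengths of the surrogate segments ship
  as an editable configuration (`default_junction_geometry()`): SVC limb
  4.5 x 25 mm, dilated IVC pouch 16 x 45 mm, LPA 4.3 x 15 mm, RPA
  4.8 x 15 mm, fenestration 2.0 x 8 mm, native wall 1 MPa / 0.5 mm
  (the calibrated wall reported for the pre-intervention model). The
  pouch radius encodes "severe dilation" — roughly four times the SVC
  calibre — and its compliance is lumped at the IVC-pathway node, since
  the aneurysm bulges proximal to the confluence. Measurement faces keep
  native calibres (the acquisition planes sit on native vessel).
* **Pouch dissipation.** Swirling-flow loss cannot emerge from a 0D
  network, so the IVC limb carries an extra series resistance
  `pouch_loss_R`. Its default (0.015 Pa s mm^-3) was fixed once, at the
  largest value for which the virtual revision still *raises* the mean
  IVC pressure — the directional response the intervention analysis
  exists to probe (see *Limitations* for the trade-off against the
  junction's energy efficiency).
* **Unstressed volume** `V_rest` defaults to 0, and the fenestration
  Windkessel's distal reference is the atrial pressure; the pulmonary
  beds reference 0 Pa. `K_s` is carried in the valve block but inert by
  default (an optional linear `rho K_s q` term), since its governing
  equation is not specified.

## Numerics

The network is integrated with `deSolve::lsoda` through a compiled-C
right-hand side (relative tolerance 1e-6, absolute 1e-8, maximum step
T/400), cycle by cycle, until the cycle means of every monitored face
pressure and flow change by less than 1e-4 (relative) between
consecutive cycles; only the final cycle is returned, on a uniform
400-interval grid. The tight periodicity tolerance is deliberate:
per-beat retrograde volumes are small differences of large oscillating
quantities, and at a looser 1e-3 they still drift by several percent
after the means have settled.

Two non-smooth elements needed care. The tricuspid diode is implemented
as a smooth reverse-blocking resistance — a logistic blend (width
5 mm^3 s^-1) between `R_TV` forward and `R_TV + 100 Pa s mm^-3` in
reverse — because an ideal switch creates a sliding mode at zero flow
that stalls adaptive stiff solvers; the residual reverse leak is below
0.2% of the stroke volume. The aortic valve state is clamped to [0, 1]
inside the right-hand side, with one-sided rates so the bounds are
invariant. Diagnostic switches (`freeze_elastance`,
`force_valves_open`) reduce the system to a resistive network whose
steady state is checked in the tests against an independent nodal
conductance solve.

## Calibration

`calibrate()` minimises a tolerance-weighted sum of squared relative
residuals — mean flows (SVC, IVC, LPA, RPA) weighted by the 2% flow
tolerance, per-beat retrograde volumes (IVC, LPA, RPA) by 7%, and
systolic/diastolic/mean pressures at the four faces by 5% — over
log-transformed multiplicative scales of the free parameters, with
Nelder-Mead. Log-scales respect positivity and the two-orders-of-
magnitude spread of the Windkessel values. The search runs once from
the caller's start and restarts once from an analytic seed
(`initialize_parameters()`: Ohmic resistance seeds for the pulmonary
beds from mean pressure over mean flow, a pressure-drop seed for the
pouch loss); the better end point wins. Simulated summaries are passed
through the same 40-phase observation operator as the clinical targets,
so the comparison is like with like.

Identifiability has a documented limit: mean summaries constrain the
*total* resistance of a bed, not the proximal/distal split, so the
resistance scales act jointly on `R_p` and `R_d`; the recovery tests
assert bed totals, not the split. The systemic beds are seeded at their
current values because no arterial-side targets exist to seed them
analytically.

## The synthetic clinical scenario

`generate_dataset()` emulates the clinical acquisitions from a known
ground truth: cardiac-gated PC-MRI-like flow waveforms resampled to 40
phases per cycle with multiplicative Gaussian noise (default SD 3% of
the signal — velocity-encoding error grows with the signal), and
catheter-like pressure waveforms on the fine grid with additive
Gaussian noise (default SD 2% of the face pulse pressure). Ventricular
descriptors (EDV, ESV, EDP, ESP) are read off the ground-truth volume
and pressure traces, and the full ground-truth parameter record rides
along as provenance. The default scenario (`default_scenario()`) is the
index patient: cycle length 0.8 s, BSA 0.51 m^2, mean IVC/Fontan
pressure about 14 mmHg, pronounced hepatic venous reflux
(about 875 mm^3 per beat at the IVC face).

What the generator does *not* emulate: beat-to-beat variability,
respiratory modulation of caval flow (a large effect in real Fontan
physiology), luminal-area waveforms, oxygen saturations, and imaging
artefacts. Passing the round-trip tests therefore shows that the
calibration machinery recovers a model of the same family under
acquisition-like noise — not that it would absorb the full messiness of
real catheter-lab data.

## What the default model reproduces, and what it cannot

With the tabulated heart and Windkessel values and the default
surrogate, the converged pre-intervention cycle shows a mean
IVC-pathway pressure of about 14.1 mmHg, an inlet energy flux of about
2.3e7 g mm^2 s^-3, hepatic reflux at the IVC face, and a 40:60 LPA:RPA
flow split. Applying the endograft operator with every upstream and
downstream parameter frozen raises the mean IVC and SVC pressures,
lowers the total caval inflow, raises both pulmonary outflows (the
excluded fenestration flow is re-routed through the lungs), and cuts
the junction's face-flux energy dissipation — the directional
picture of the reported revision analysis.

Two reported reference numbers are structurally out of reach of this 0D
reduction, and the package reports them honestly rather than absorbing
them:

* **Cardiac index 2.4 L min^-1 m^-2.** With the tabulated pulmonary
  Windkessels (parallel resistance about 0.163 Pa s mm^-3 referenced to
  0 Pa) a pathway pressure of 15 mmHg admits about 12,300 mm^3 s^-1 of
  trans-pulmonary flow plus about 800 mm^3 s^-1 through the
  fenestration — a cardiac index near 1.4 at BSA 0.51 m^2. A cardiac
  index of 2.4 would require a mean pathway pressure near 24 mmHg with
  the same resistances. The reported inlet energy flux
  (2.39e7 g mm^2 s^-3 at about 2000 Pa) itself implies a total caval flow near
  1.2e4 mm^3 s^-1, i.e. the lower figure; the model sits where the
  printed parameters put it.
* **Post-intervention IVC pulse-pressure rise and the 88% junction
  efficiency, jointly.** At 0D both quantities are governed by the same
  series loss element: a pouch resistance large enough to dissipate 12%
  of the inlet energy flux dominates the pathway's pulsatile impedance,
  so removing it with the graft *drops* the IVC pulse pressure, while a
  pouch resistance small enough to let the stiff graft raise the pulse
  leaves the junction near 95% efficient. In a full 3D
  fluid-structure model the dissipation lives in swirl (kinetic exchange at little mean pressure
  cost) and the pulse rise in wall mechanics — mechanisms a 0D network
  cannot separate. The default keeps the directional mean-pressure,
  flow and dissipation responses and concedes the pulse sign; the
  energy-accounting operations themselves reproduce the reference
  efficiency arithmetic exactly.

## Problem sizes

The shipped configuration runs everything at desk scale: 400 output
points per cycle, typically 10-15 cycles to periodicity (about 50 ms
per converged simulation), a 300-evaluation calibration budget (about
10 s), and 40-phase synthetic acquisitions. These sizes are the
package's defaults, chosen so a full pre/post pipeline with calibration
completes in well under a minute.
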