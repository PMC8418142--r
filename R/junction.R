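#' Default pre-intervention pathway geometry
#'
#' Segment radii and lengths (mm) of the reduced-order Fontan pathway:
#' SVC and dilated IVC (lateral-tunnel pouch) inlet limbs meeting at the
#' cavopulmonary confluence, LPA/RPA outlet limbs, and a short fenestration
#' neck leaving the IVC-pathway node. The inferior limb is markedly dilated
#' relative to the SVC, reflecting the aneurysmal pouch; the measurement
#' faces (where flows/pressures are reported) carry native caval/pulmonary
#' calibres.
#'
#' @return a named list of `c(radius =, length =)` pairs plus face radii.
#' @export
default_junction_geometry <- function() {
  list(
    svc  = c(radius = 4.5, length = 25),
    ivc  = c(radius = 16,  length = 45),
    lpa  = c(radius = 4.3, length = 15),
    rpa  = c(radius = 4.8, length = 15),
    fen  = c(radius = 2.0, length = 8),
    face_radius = c(svc = 4.5, ivc = 7, lpa = 4.3, rpa = 4.8, fen = 2.0)
  )
}

#' Build the pre-intervention junction surrogate
#'
#' Reduces each pathway segment to lumped R/L/C with
#' [tube_segment_reduce()], assigns half of each segment compliance to its
#' end nodes, and attaches the fenestration branch and the extra pouch
#' dissipation resistance. The pouch loss resistance stands in for the
#' swirling-flow losses of the dilated pathway, which a 0D network cannot
#' produce from geometry alone; its default is calibrated so the
#' pre-intervention junction transmits energy with the efficiency expected
#' for this pathology (see the methods vignette).
#'
#' @param geometry segment geometry, as from [default_junction_geometry()].
#' @param wall_stiffness native wall elastic modulus, Pa.
#' @param wall_thickness native wall thickness, mm.
#' @param pouch_loss_R extra series resistance on the IVC-to-confluence
#'   segment, Pa s mm^-3.
#' @param mu dynamic viscosity, Pa s.
#' @param rho blood density, g mm^-3.
#' @param fenestration_present logical; include the fenestration branch.
#' @return an object of class `junction_surrogate`.
#' @export
build_pre_junction <- function(geometry = default_junction_geometry(),
                               wall_stiffness = 1e6, wall_thickness = 0.5,
                               pouch_loss_R = 0.02,
                               mu = 0.004, rho = 0.00106,
                               fenestration_present = TRUE) {
  needed <- c("svc", "ivc", "lpa", "rpa", "fen")
  missing <- setdiff(needed, names(geometry))
  if (length(missing) > 0) {
    stop("missing junction segment(s): ", paste(missing, collapse = ", "))
  }
  for (s in needed) {
    g <- geometry[[s]]
    if (any(g[c("radius", "length")] <= 0)) {
      stop("segment `", s, "` must have positive radius and length")
    }
  }
  if (geometry$ivc["radius"] <= geometry$svc["radius"]) {
    warning("IVC pathway radius does not exceed SVC radius; ",
            "pre-intervention pathway is expected to be dilated")
  }
  stopifnot(pouch_loss_R >= 0)
  segs <- lapply(needed, function(s) {
    g <- geometry[[s]]
    tube_segment(s, g["radius"], g["length"], wall_stiffness,
                 wall_thickness, mu, rho)
  })
  names(segs) <- needed
  jn <- structure(list(
    segments = segs,
    pouch_loss_R = pouch_loss_R,
    fenestration_present = fenestration_present,
    face_areas = pi * geometry$face_radius^2,
    mu = mu, rho = rho
  ), class = "junction_surrogate")
  jn$node_compliances <- junction_node_compliances(jn)
  jn
}

# Segment compliances lumped at the surrogate nodes (svc inlet,
# ivc-pathway, confluence): half of each limb's compliance at each of its
# end nodes, except the IVC limb, whose compliance sits entirely at the
# IVC-pathway node -- the aneurysmal pouch bulges proximal to the
# confluence, which itself stays near native calibre.
junction_node_compliances <- function(jn) {
  s <- jn$segments
  fenC <- if (jn$fenestration_present) s$fen$C else 0
  c(svc  = s$svc$C / 2,
    ivc  = s$ivc$C + fenC / 2,
    conf = s$svc$C / 2 + s$lpa$C / 2 + s$rpa$C / 2)
}

#' Total junction compliance
#' @param jn a `junction_surrogate`.
#' @return total lumped compliance of the pathway nodes, mm^3 Pa^-1.
#' @export
junction_total_compliance <- function(jn) sum(jn$node_compliances)

#' Series resistance of the IVC-to-pulmonary pathway
#' @param jn a `junction_surrogate`.
#' @return IVC segment resistance (including pouch loss) plus the smaller
#'   of the two pulmonary segment resistances, Pa s mm^-3.
#' @export
junction_ivc_path_resistance <- function(jn) {
  jn$segments$ivc$R + jn$pouch_loss_R +
    min(jn$segments$lpa$R, jn$segments$rpa$R)
}

#' Bifurcated endograft specification
#'
#' Dimensions and wall properties of the custom bifurcated endograft:
#' a main body deployed from the IVC to the pulmonary ostium and a limb
#' deployed into the SVC.
#'
#' @param main_body_diameter mm.
#' @param limb_diameter mm.
#' @param stiffness graft wall elastic modulus, Pa.
#' @param thickness graft wall thickness, mm.
#' @param main_body_length mm.
#' @param limb_length mm.
#' @return an object of class `endograft_spec`.
#' @export
endograft_spec <- function(main_body_diameter = 10, limb_diameter = 8,
                           stiffness = 12e6, thickness = 0.22,
                           main_body_length = 40, limb_length = 25) {
  stopifnot(main_body_diameter > 0, limb_diameter > 0, stiffness > 0,
            thickness > 0, main_body_length > 0, limb_length > 0)
  structure(list(main_body_diameter = main_body_diameter,
                 limb_diameter = limb_diameter,
                 stiffness = stiffness, thickness = thickness,
                 main_body_length = main_body_length,
                 limb_length = limb_length),
            class = "endograft_spec")
}

#' Apply the virtual endovascular revision
#'
#' Replaces the dilated IVC pathway by the endograft main body and the SVC
#' limb by the graft limb (graft wall properties replace the native wall
#' along the covered segments), removes the pouch loss resistance, and
#' excludes the fenestration. Outlet (pulmonary) segments keep their native
#' wall. Measurement face areas are unchanged (the acquisition planes sit
#' on native vessel).
#'
#' @param pre a pre-intervention `junction_surrogate`.
#' @param graft an [endograft_spec()].
#' @param mu dynamic viscosity, Pa s.
#' @param rho blood density, g mm^-3.
#' @return a post-intervention `junction_surrogate`.
#' @export
apply_endograft <- function(pre, graft = endograft_spec(),
                            mu = pre$mu, rho = pre$rho) {
  stopifnot(inherits(pre, "junction_surrogate"),
            inherits(graft, "endograft_spec"))
  r_main <- graft$main_body_diameter / 2
  r_limb <- graft$limb_diameter / 2
  if (r_main >= pre$segments$ivc$radius) {
    warning("graft main body is not smaller than the native pathway; ",
            "no exclusion of the dilated segment")
  }
  post <- pre
  post$segments$ivc <- tube_segment("ivc", r_main, graft$main_body_length,
                                    graft$stiffness, graft$thickness,
                                    mu, rho)
  post$segments$svc <- tube_segment("svc", r_limb, graft$limb_length,
                                    graft$stiffness, graft$thickness,
                                    mu, rho)
  post$pouch_loss_R <- 0
  post$fenestration_present <- FALSE
  post$node_compliances <- junction_node_compliances(post)
  post
}
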