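#' Unit conversions
#'
#' The package works internally in the g-mm-s unit system: pressure in Pa
#' (1 Pa = 1 g mm^-1 s^-2), volume in mm^3, flow in mm^3 s^-1, density in
#' g mm^-3. Clinical quantities are accepted and reported in mmHg, mL and
#' L min^-1 m^-2 at the I/O layer only; these helpers convert between the
#' two systems.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmHg_to_Pa(15)    # mean Fontan pressure target, ~2000 Pa
#' Pa_to_mmHg(933.3) # ~7 mmHg
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname units
#' @export
mL_to_mm3 <- function(x) x * 1000

#' @rdname units
#' @export
mm3_to_mL <- function(x) x / 1000

#' Cardiac index from mean flow
#'
#' Converts a cycle-averaged flow in mm^3 s^-1 to a cardiac index in
#' L min^-1 m^-2 given the body surface area.
#'
#' @param q_mean mean flow (mm^3 s^-1).
#' @param bsa body surface area (m^2).
#' @return cardiac index (L min^-1 m^-2).
#' @export
cardiac_index <- function(q_mean, bsa) {
  stopifnot(is.finite(q_mean), bsa > 0)
  (q_mean * 60 / 1e6) / bsa
}
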