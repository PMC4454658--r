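#' USAF-1951 resolving power
#'
#' Resolving power of a USAF-1951 three-bar pattern, in line pairs per mm:
#' `R = 2^(group + (element - 1) / 6)`, and the corresponding line-pair
#' period in micrometres at 1:1 magnification, `1000 / R`.
#'
#' @param group Integer group number (may be negative).
#' @param element Element number within the group, 1 to 6.
#' @return List with `lp_mm` and `period_um`.
#' @examples
#' usaf_resolution(6, 4) # about 90 lp/mm, 11 um line-pair period
#' @export
usaf_resolution <- function(group, element) {
  check_number(group, "group")
  check_number(element, "element")
  if (element < 1 || element > 6 || element != round(element))
    stopf("'element' must be an integer in 1..6")
  R <- 2^(group + (element - 1) / 6)
  list(lp_mm = R, period_um = 1000 / R)
}

#' Line-pair period from a resolving power
#'
#' @param lp_mm Resolving power in line pairs per mm.
#' @return Line-pair period in micrometres at 1:1 magnification.
#' @examples
#' line_pair_period(28.5) # about 35 um
#' @export
line_pair_period <- function(lp_mm) {
  check_number(lp_mm, "lp_mm", min = 0, strict_min = TRUE)
  1000 / lp_mm
}

#' Depth of field of a symmetrical lens
#'
#' `DOF = 2 s N c f^2 (s - f) / (f^4 - N^2 c^2 (s - f)^2)`, where `s` is
#' the lens-to-focus distance, `N` the f-number, `f` the focal length and
#' `c` the circle of confusion (largest blur spot still treated as in
#' focus, conventionally twice the sensor pixel size). All distances in
#' mm. The formula is only valid short of the hyperfocal regime, where the
#' denominator stays positive.
#'
#' @param s Distance from the lens to the focus point (mm), `> f`.
#' @param N f-number (focal length / aperture diameter).
#' @param f Focal length (mm), default 105.
#' @param c Circle of confusion (mm), default 0.010 (twice a 4.9 um pixel,
#'   rounded).
#' @return Depth of field in mm.
#' @examples
#' depth_of_field(s = 400, N = 32) # about 6.85 mm
#' @export
depth_of_field <- function(s, N, f = 105, c = 0.010) {
  check_number(s, "s", min = 0, strict_min = TRUE)
  check_number(N, "N", min = 0, strict_min = TRUE)
  check_number(f, "f", min = 0, strict_min = TRUE)
  check_number(c, "c", min = 0, strict_min = TRUE)
  if (s <= f) stopf("'s' must exceed the focal length f")
  den <- f^4 - N^2 * c^2 * (s - f)^2
  if (den <= 0)
    stopf("focus distance is at or beyond the hyperfocal distance (denominator %.4g <= 0)",
          den)
  2 * s * N * c * f^2 * (s - f) / den
}

#' Nyquist-limited feature size
#'
#' The smallest resolvable feature allowed by sensor sampling: twice the
#' pixel pitch, scaled back to object space by the magnification.
#'
#' @param pixel_pitch_um Sensor pixel pitch (micrometres).
#' @param magnification Reproduction ratio (1 for 1:1 macro work).
#' @return Feature size in micrometres on the object.
#' @examples
#' nyquist_feature(4.9, 1) # 9.8 um
#' @export
nyquist_feature <- function(pixel_pitch_um, magnification = 1) {
  check_number(pixel_pitch_um, "pixel_pitch_um", min = 0)
  check_number(magnification, "magnification", min = 0, strict_min = TRUE)
  2 * pixel_pitch_um / magnification
}
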