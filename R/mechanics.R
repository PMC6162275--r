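#' Arc displacement of a rotated attachment point
#'
#' A point at radial distance `r` from the rotation axis, rotated by `phi`
#' degrees, travels an arc of `2 * pi * r * phi / 360`. Linear in both
#' arguments; angles stay in degrees throughout the mechanics module.
#'
#' @param r radial distance, nm (> 0).
#' @param phi rotation, degrees.
#' @return arc length, nm.
#' @export
arc_displacement <- function(r, phi) {
  stopifnot(all(r > 0))
  2 * pi * r * phi / 360
}

#' Iris-diaphragm lever model of the gating ring
#'
#' The C-linker disk is modelled as a rigid type-2 lever with two
#' attachment radii: the CNBDs at `r_cnbd` (~3 nm from the pore axis) and
#' the S6 bundle-crossing helices at `r_s6` (~1 nm). A clockwise rotation
#' `phi` of the CNBDs displaces their attachment by the arc
#' `2*pi*r_cnbd*phi/360`; the S6 attachment moves by the same angle on the
#' smaller radius, so its displacement is divided by `r_cnbd/r_s6` while
#' the transmitted force is amplified by the same factor (the net moment
#' on a rigid lever is zero). The pore (bundle-crossing) diameter change
#' is twice the S6 displacement.
#'
#' @param r_cnbd,r_s6 attachment radii, nm.
#' @param phi CNBD rotation, degrees CW.
#' @return list `dx_cnbd_nm`, `dx_s6_nm`, `force_amplification`,
#'   `pore_diameter_change_nm`.
#' @export
lever_transform <- function(r_cnbd = 3, r_s6 = 1, phi = 25) {
  stopifnot(r_cnbd > 0, r_s6 > 0)
  dx_cnbd <- arc_displacement(r_cnbd, phi)
  dx_s6 <- dx_cnbd * r_s6 / r_cnbd
  list(dx_cnbd_nm = dx_cnbd,
       dx_s6_nm = dx_s6,
       force_amplification = r_cnbd / r_s6,
       pore_diameter_change_nm = 2 * dx_s6)
}

#' Oscillating-mode tip-sample force estimate
#'
#' Evaluates `F = kc * sqrt((1 - alpha) * (A0^2 - As^2)) / Qc` in SI
#' units: the standard estimate of the peak force applied by an
#' amplitude-modulation AFM cantilever, from the free amplitude `A0`, the
#' setpoint amplitude `As`, the fraction `alpha` of the amplitude
#' reduction caused by frequency shift (typically 0.5), the spring
#' constant `kc` and the quality factor `Qc` in liquid.
#'
#' @param kc spring constant, N/m.
#' @param Qc quality factor (dimensionless, > 0).
#' @param A0 free amplitude, m.
#' @param As setpoint amplitude, m (0 <= As <= A0).
#' @param alpha frequency-shift fraction in [0, 1].
#' @return force in newtons.
#' @export
tip_force <- function(kc = 0.15, Qc = 1.5, A0 = 1e-9, As = 0.9e-9, alpha = 0.5) {
  stopifnot(kc > 0, Qc > 0, alpha >= 0, alpha <= 1, A0 >= 0)
  if (any(As > A0)) stop("setpoint amplitude exceeds free amplitude", call. = FALSE)
  kc * sqrt((1 - alpha) * (A0^2 - As^2)) / Qc
}

#' Conservative vertical displacement estimate
#'
#' The vertical CNBD movement is bounded by the height differences measured
#' against the upper and lower molecules of the alternating packing; the
#' conservative point estimate is their arithmetic mean.
#'
#' @param dz_high,dz_low the two measured height differences, nm (>= 0).
#' @return mean, nm.
#' @export
vertical_displacement_estimate <- function(dz_high, dz_low) {
  stopifnot(dz_high >= 0, dz_low >= 0)
  (dz_high + dz_low) / 2
}
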