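#' Anisotropic diffusion medium
#'
#' Free-diffusion medium with an individual diffusivity per axis. Under
#' cylinder symmetry `Dx = Dy = D_perp` and `Dz = D_par`; the anisotropy is
#' summarised by the ratio \eqn{r = D_\perp / D_\parallel}.
#'
#' @param Dx,Dy,Dz Diffusivities, m^2 s^-1 (all >= 0).
#' @return An object of class `medium`.
#' @export
medium <- function(Dx, Dy, Dz) {
  d <- c(Dx = Dx, Dy = Dy, Dz = Dz)
  if (any(!is.finite(d)) || any(d < 0))
    stop_invalid("diffusivities must be finite and >= 0")
  structure(as.list(d), class = "medium")
}

#' @rdname medium
#' @param D_par Longitudinal diffusivity (along the cylinder axis), m^2 s^-1.
#' @param ratio Transverse-to-longitudinal ratio `D_perp / D_par` in `[0, 1]`.
#' @export
medium_cylinder <- function(D_par, ratio) {
  if (ratio < 0) stop_invalid("'ratio' must be >= 0")
  medium(ratio * D_par, ratio * D_par, D_par)
}

#' Ensemble net phase under a linear gradient
#'
#' For free diffusion from the voxel centre under a linear gradient the
#' ensemble phase integrand is odd in z, so integrated over symmetric voxel
#' borders the net phase is exactly zero: the motion tempers the magnitude
#' (see [magnitude_attenuation()]) and leaves no phase signature. Provided
#' for symmetry of the model API.
#'
#' @return 0 (rad), exactly.
#' @export
phase_linear_ensemble <- function() 0

#' Ensemble net phase under a 1D quadratic gradient
#'
#' Closed form \eqn{\varphi_2 = -2 \gamma G_2 D \delta \Delta} for free 1D
#' diffusion from the origin under \eqn{B_z = G_2 z^2} with rectangular
#' pulses, in the infinite-voxel-border approximation.
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @param G2 Field curvature, T m^-2.
#' @param D Diffusivity, m^2 s^-1.
#' @param timing A [pulse_timing()] (rectangular shape).
#' @return Net phase, rad.
#' @export
phase_quadratic_1d <- function(gamma, G2, D, timing) {
  stopifnot(inherits(timing, "pulse_timing"))
  if (D < 0) stop_invalid("'D' must be >= 0")
  -2 * gamma * G2 * D * timing$delta * timing$Delta
}

#' Ensemble net phase under the 3D Z2 field
#'
#' \eqn{\varphi_{2,3D} = -2\gamma G_2 \delta \Delta (D_z - (D_x + D_y)/2)}
#' for free anisotropic diffusion under the Z2 field. Isotropic media give
#' exactly zero (the field's Laplacian vanishes); only anisotropy leaves a
#' net phase.
#'
#' @inheritParams phase_quadratic_1d
#' @param med A [medium()].
#' @return Net phase, rad.
#' @export
phase_z2_3d <- function(gamma, G2, med, timing) {
  stopifnot(inherits(med, "medium"), inherits(timing, "pulse_timing"))
  -2 * gamma * G2 * timing$delta * timing$Delta *
    (med$Dz - 0.5 * (med$Dx + med$Dy))
}

#' Ensemble net phase under cylinder symmetry
#'
#' \eqn{\varphi = -2\gamma G_2 \delta \Delta D_\parallel (1 - r)} with
#' \eqn{r = D_\perp / D_\parallel}; the cylinder-symmetric special case of
#' [phase_z2_3d()].
#'
#' @inheritParams phase_quadratic_1d
#' @param D_par Longitudinal diffusivity, m^2 s^-1.
#' @param ratio `D_perp / D_par`.
#' @return Net phase, rad.
#' @export
phase_cylinder <- function(gamma, G2, D_par, ratio, timing) {
  stopifnot(inherits(timing, "pulse_timing"))
  if (D_par < 0 || ratio < 0) stop_invalid("'D_par' and 'ratio' must be >= 0")
  -2 * gamma * G2 * timing$delta * timing$Delta * D_par * (1 - ratio)
}

#' Convert between fractional anisotropy and the diffusivity ratio
#'
#' Under cylinder symmetry with eigenvalues `(r D, r D, D)` the fractional
#' anisotropy is \eqn{FA = (1 - r) / \sqrt{1 + 2 r^2}}. `ratio_from_fa()`
#' inverts this on `r` in `[0, 1]`; the two functions are mutual inverses.
#'
#' @param FA Fractional anisotropy in `[0, 1]` (1 is the stick limit, r = 0).
#' @param ratio Diffusivity ratio in `[0, 1]`.
#' @return The corresponding ratio or FA.
#' @examples
#' ratio_from_fa(0.5)               # 0.4189...
#' fa_from_ratio(ratio_from_fa(0.5))
#' @export
ratio_from_fa <- function(FA) {
  if (FA < 0 || FA > 1) stop_invalid("'FA' must be in [0, 1]")
  if (FA == 0) return(1)
  if (FA == 1) return(0)
  a <- 1 - 2 * FA^2
  disc <- FA^2 * (3 - 2 * FA^2)
  if (disc < 0) stop_invalid("no diffusivity ratio in [0, 1] for this FA")
  if (abs(a) < 1e-12) return((1 - FA^2) / 2)  # FA = 1/sqrt(2): linear case
  r <- (1 - FA * sqrt(3 - 2 * FA^2)) / a
  if (r < -1e-12 || r > 1 + 1e-12)
    stop_invalid("no diffusivity ratio in [0, 1] for this FA")
  min(max(r, 0), 1)
}

#' @rdname ratio_from_fa
#' @export
fa_from_ratio <- function(ratio) {
  if (ratio < 0 || ratio > 1) stop_invalid("'ratio' must be in [0, 1]")
  (1 - ratio) / sqrt(1 + 2 * ratio^2)
}

#' Predicted phase difference between two separation times
#'
#' Experiment-level prediction for a cylinder-symmetric sample measured at
#' two pulse separations with the same pulse duration and shape:
#' \eqn{[\varphi(\Delta_2) - \varphi(\Delta_1)]} from [phase_cylinder()]
#' with `r` solved from the sample's FA, multiplied by the pulse-shape
#' moment factor ([effective_moment_factor()]; 2/pi for half-sine pulses).
#'
#' @inheritParams phase_quadratic_1d
#' @param timing1,timing2 [pulse_timing()] objects sharing `delta` and shape.
#' @param D_par Longitudinal diffusivity, m^2 s^-1.
#' @param FA Fractional anisotropy of the sample.
#' @return Phase difference, rad.
#' @examples
#' t1 <- pulse_timing(0.03, 0.243, shape = "half_sine")
#' t2 <- pulse_timing(0.03, 0.443, shape = "half_sine")
#' 1e3 * predict_experiment_phase_difference(2.675e8, 9.6, t1, t2,
#'                                           D_par = 2.0e-9, FA = 0.5)
#' @export
predict_experiment_phase_difference <- function(gamma, G2, timing1, timing2,
                                                D_par, FA) {
  stopifnot(inherits(timing1, "pulse_timing"), inherits(timing2, "pulse_timing"))
  if (abs(timing1$delta - timing2$delta) > 1e-12 ||
      timing1$shape != timing2$shape)
    stop_invalid("the two timings must share 'delta' and 'shape'")
  r <- ratio_from_fa(FA)
  dphi <- phase_cylinder(gamma, G2, D_par, r, timing2) -
          phase_cylinder(gamma, G2, D_par, r, timing1)
  dphi * effective_moment_factor(timing1$shape)
}

#' Signal magnitude attenuation under a linear gradient
#'
#' Monoexponential decay \eqn{S(b) = S_0 \exp(-bD)}.
#'
#' @param S0 Unweighted signal.
#' @param b b-value, s m^-2 (SI).
#' @param D Diffusivity, m^2 s^-1.
#' @return Attenuated signal.
#' @export
magnitude_attenuation <- function(S0, b, D) {
  if (any(b < 0) || any(D < 0)) stop_invalid("'b' and 'D' must be >= 0")
  S0 * exp(-b * D)
}
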