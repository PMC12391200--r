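#' Ionic environment of the bathing solution
#'
#' @param c_star Bath salt (NaCl) concentration, mM; each ion species is
#'   present at this concentration. Default 150 mM (physiological saline).
#' @param temperature Absolute temperature, K. Default 298 K (benchtop
#'   testing); use 310 K for body temperature.
#' @return An object of class `ion_environment` (gas constant
#'   R = 8.314 J mol^-1 K^-1 is fixed).
#' @export
ion_environment <- function(c_star = 150, temperature = 298) {
  if (!is.finite(c_star) || c_star < 0) stop("c_star must be >= 0")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  structure(list(c_star = c_star, temperature = temperature, R = 8.314),
            class = "ion_environment")
}

#' Ideal Donnan osmotic pressure
#'
#' Osmotic pressure exerted by a tissue with fixed charge density `c_F`
#' equilibrated against a monovalent salt bath of concentration `c_star`,
#' with ideal activity and osmotic coefficients:
#' \deqn{\pi = R T \left(\sqrt{c_F^2 + 4 c^{*2}} - 2 c^*\right).}
#' The expression follows from electroneutrality plus equality of the ion
#' products inside and outside the tissue. Concentrations in mM are per
#' litre of interstitial water, numerically equal to mol m^-3, so the result
#' is in Pa.
#'
#' @param c_F Fixed charge density, mM (vectorized).
#' @param env An [ion_environment()].
#' @return Osmotic pressure, Pa.
#' @examples
#' donnan_pressure(182.2, ion_environment()) / 1e3  # about 126 kPa
#' @export
donnan_pressure <- function(c_F, env = ion_environment()) {
  stopifnot(inherits(env, "ion_environment"))
  if (any(!is.finite(c_F)) || any(c_F < 0)) stop("c_F must be >= 0")
  env$R * env$temperature *
    (sqrt(c_F^2 + 4 * env$c_star^2) - 2 * env$c_star)
}

#' Deformation-dependent fixed charge density
#'
#' Fixed charges are bound to the solid matrix, so compression concentrates
#' them in the shrinking interstitial water volume. With reference porosity
#' `phi_w0` and volume ratio `J` (current / reference volume), mixture
#' kinematics with an incompressible solid give
#' \deqn{c_F = c_{F0}\,\frac{\phi_{w0}}{J - 1 + \phi_{w0}}.}
#'
#' @param c_F0 Reference fixed charge density, mM.
#' @param phi_w0 Reference porosity, in `(0, 1)`.
#' @param J Volume ratio (vectorized); must exceed `1 - phi_w0` (the pore
#'   space must not be exhausted).
#' @return Current fixed charge density, mM.
#' @export
fcd_deformed <- function(c_F0, phi_w0, J) {
  if (!is.finite(c_F0) || c_F0 < 0) stop("c_F0 must be >= 0")
  if (!is.finite(phi_w0) || phi_w0 <= 0 || phi_w0 >= 1)
    stop("phi_w0 must lie in (0, 1)")
  if (any(!is.finite(J)) || any(J <= 1 - phi_w0))
    stop("pore collapse: J must exceed 1 - phi_w0")
  c_F0 * phi_w0 / (J - 1 + phi_w0)
}
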