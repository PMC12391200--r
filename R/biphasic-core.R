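#' Biphasic material parameter set
#'
#' Bundles the linear biphasic (poroelastic) constitutive parameters of a
#' hydrated cartilaginous tissue: the equilibrium aggregate modulus `H_A`
#' (confined-compression stiffness of the drained solid matrix), the hydraulic
#' permeability `k` governing interstitial fluid flow, the Poisson ratio of
#' the solid matrix, the reference porosity (water volume fraction) and an
#' optional reference fixed charge density used by the Donnan swelling model.
#'
#' All values are SI: Pa for `H_A`, m^4 N^-1 s^-1 for `k`. Fixed charge
#' density is in mol per m^3 of interstitial water (numerically equal to mM
#' and to mEq/L for monovalent charges).
#'
#' @param H_A Aggregate modulus, Pa. Must be positive.
#' @param k Hydraulic permeability, m^4 N^-1 s^-1. Must be positive.
#' @param nu Poisson ratio of the solid matrix, in `[0, 0.5)`.
#' @param phi_w0 Reference porosity (water volume fraction), in `(0, 1)`.
#' @param c_F0 Reference fixed charge density, mM (per volume of interstitial
#'   water). Zero disables osmotic swelling.
#' @return An object of class `biphasic_material`.
#' @examples
#' np <- biphasic_material(H_A = 0.44e6, k = 2.96e-16, phi_w0 = 0.873)
#' np$H_A / 1e6
#' @export
biphasic_material <- function(H_A, k, nu = 0.2, phi_w0 = 0.8, c_F0 = 0) {
  stopifnot(is.numeric(H_A), length(H_A) == 1L, is.finite(H_A),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (H_A <= 0) stop("aggregate modulus H_A must be positive")
  if (k <= 0) stop("hydraulic permeability k must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson ratio nu must lie in [0, 0.5)")
  if (!is.finite(phi_w0) || phi_w0 <= 0 || phi_w0 >= 1)
    stop("reference porosity phi_w0 must lie in (0, 1)")
  if (!is.finite(c_F0) || c_F0 < 0)
    stop("fixed charge density c_F0 must be non-negative")
  structure(list(H_A = H_A, k = k, nu = nu, phi_w0 = phi_w0, c_F0 = c_F0),
            class = "biphasic_material")
}

#' @export
print.biphasic_material <- function(x, ...) {
  cat(sprintf(
    "<biphasic_material> H_A = %.4g MPa, k = %.4g x 1e-16 m^4/N/s, nu = %.3g\n",
    x$H_A / 1e6, x$k / 1e-16, x$nu))
  cat(sprintf("  porosity phi_w0 = %.3f, FCD c_F0 = %.1f mM\n",
              x$phi_w0, x$c_F0))
  invisible(x)
}

#' Cylindrical specimen geometry
#'
#' @param thickness Specimen thickness, m.
#' @param diameter Specimen diameter, m. Default 5 mm (standard trephine).
#' @return An object of class `specimen_geometry` with the derived
#'   cross-sectional area `area = pi * diameter^2 / 4` (m^2).
#' @export
specimen_geometry <- function(thickness, diameter = 5e-3) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L,
            is.numeric(diameter), length(diameter) == 1L)
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be > 0")
  structure(list(thickness = thickness, diameter = diameter,
                 area = pi * diameter^2 / 4),
            class = "specimen_geometry")
}

#' Confined-compression test protocol
#'
#' Describes the two-phase protocol used for regional disc specimens: an
#' offset-compression stress-relaxation phase (default 10% strain held for
#' 1 h) followed by a creep phase in which an additional load equal to a
#' fraction (default 20%) of the relaxation equilibrium load is applied over a
#' linear ramp (default 5 min) and held (default 2 h).
#'
#' @param offset_strain Offset compressive strain applied before relaxation.
#' @param relax_duration Stress-relaxation hold, s.
#' @param creep_load_fraction Creep load as a fraction of the relaxation
#'   equilibrium load.
#' @param ramp_duration Creep load ramp time, s.
#' @param creep_duration Creep hold, s.
#' @param pbs_replenish_interval Bath replenishment interval, s (metadata
#'   only; does not enter any computation).
#' @return An object of class `load_protocol`.
#' @export
load_protocol <- function(offset_strain = 0.10, relax_duration = 3600,
                          creep_load_fraction = 0.20, ramp_duration = 300,
                          creep_duration = 7200,
                          pbs_replenish_interval = 900) {
  if (!is.finite(offset_strain) || offset_strain <= 0 || offset_strain >= 1)
    stop("offset_strain must lie in (0, 1)")
  if (!is.finite(creep_load_fraction) || creep_load_fraction <= 0 ||
      creep_load_fraction >= 1)
    stop("creep_load_fraction must lie in (0, 1)")
  for (d in c(relax_duration, ramp_duration, creep_duration,
              pbs_replenish_interval))
    if (!is.finite(d) || d <= 0) stop("all protocol durations must be > 0")
  structure(list(offset_strain = offset_strain,
                 relax_duration = relax_duration,
                 creep_load_fraction = creep_load_fraction,
                 ramp_duration = ramp_duration,
                 creep_duration = creep_duration,
                 pbs_replenish_interval = pbs_replenish_interval),
            class = "load_protocol")
}

#' Series truncation control
#'
#' @param tol Relative truncation tolerance: summation stops once the next
#'   term is below `tol` times the partial sum (plus an absolute floor).
#' @param n_max Maximum number of series terms before an error is raised.
#' @return An object of class `series_control`.
#' @export
series_control <- function(tol = 1e-12, n_max = 200L) {
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0")
  if (n_max < 1) stop("n_max must be >= 1")
  structure(list(tol = tol, n_max = as.integer(n_max)),
            class = "series_control")
}

#' Young's modulus from aggregate modulus
#'
#' For an isotropic linear elastic solid matrix the confined-compression
#' aggregate modulus and Young's modulus are related through the Poisson
#' ratio: `E = H_A (1 + nu)(1 - 2 nu) / (1 - nu)`.
#'
#' @param H_A Aggregate modulus, Pa (vectorized).
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return Young's modulus in the same units as `H_A`.
#' @examples
#' young_from_aggregate(1.19e6, 0.2) / 1e6  # 1.07 MPa
#' @export
young_from_aggregate <- function(H_A, nu) {
  if (any(!is.finite(H_A)) || any(H_A <= 0)) stop("H_A must be positive")
  if (any(!is.finite(nu)) || any(nu < 0) || any(nu >= 0.5))
    stop("nu must lie in [0, 0.5)")
  H_A * (1 + nu) * (1 - 2 * nu) / (1 - nu)
}

#' Aggregate modulus from Young's modulus
#'
#' Inverse of [young_from_aggregate()].
#'
#' @param E Young's modulus, Pa (vectorized).
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return Aggregate modulus in the same units as `E`.
#' @export
aggregate_from_young <- function(E, nu) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  if (any(!is.finite(nu)) || any(nu < 0) || any(nu >= 0.5))
    stop("nu must lie in [0, 0.5)")
  E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
}

#' Characteristic consolidation (gel diffusion) time
#'
#' `tau = h^2 / (H_A k)`, the time scale over which interstitial fluid
#' redistributes across a layer of thickness `h` draining through one face.
#'
#' @param mat A [biphasic_material()].
#' @param h Drainage path length (specimen thickness for single-sided
#'   drainage), m.
#' @return Characteristic time, s.
#' @export
gel_time <- function(mat, h) {
  stopifnot(inherits(mat, "biphasic_material"))
  if (any(!is.finite(h)) || any(h <= 0)) stop("h must be > 0")
  h^2 / (mat$H_A * mat$k)
}

#' Permeability in reporting units
#'
#' Converts SI hydraulic permeability (m^4 N^-1 s^-1) to the customary
#' reporting unit of 1e-4 mm^4 N^-1 s^-1 (so 2.75e-16 m^4/N/s reads 2.75).
#'
#' @param k_SI Permeability, m^4 N^-1 s^-1 (vectorized).
#' @return Numeric value in units of 1e-4 mm^4 N^-1 s^-1.
#' @export
permeability_to_report_units <- function(k_SI) {
  if (any(!is.finite(k_SI)) || any(k_SI < 0)) stop("k_SI must be >= 0")
  # 1 m^4 = 1e12 mm^4; report unit is 1e-4 mm^4/N/s
  k_SI * 1e12 / 1e-4
}

#' Confined-compression creep strain under a step load
#'
#' Surface (mean) compressive strain of a laterally confined biphasic layer
#' of thickness `h` draining through one face, after a step in applied
#' compressive stress `sigma0` at `t = 0`:
#' \deqn{\varepsilon(t) = \frac{\sigma_0}{H_A}\Big[1 - 2\sum_{n\ge 0}
#'   \frac{\exp(-M_n^2\, t\, H_A k / h^2)}{M_n^2}\Big],\quad
#'   M_n = (n + \tfrac12)\pi.}
#' The strain rises from 0 at `t = 0` to the drained equilibrium
#' `sigma0 / H_A`. For `t/tau < 0.05` (with `tau = h^2/(H_A k)`) the exactly
#' equivalent image (erfc) representation is evaluated instead of the
#' eigenfunction series, which keeps machine accuracy at early times where
#' the spectral series converges only algebraically.
#'
#' @param mat A [biphasic_material()].
#' @param h Layer thickness (drainage path), m.
#' @param sigma0 Applied compressive stress, Pa.
#' @param t Time(s) since load application, s (vectorized).
#' @param ctl A [series_control()].
#' @return Compressive engineering strain (dimensionless), same length as `t`.
#' @export
creep_strain_step <- function(mat, h, sigma0, t, ctl = series_control()) {
  stopifnot(inherits(mat, "biphasic_material"))
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  if (!is.finite(sigma0) || sigma0 < 0) stop("sigma0 must be >= 0")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  tau <- gel_time(mat, h)
  (sigma0 / mat$H_A) * kernel_creep_step(t / tau, ctl)
}

#' Confined-compression creep strain under a ramped load
#'
#' As [creep_strain_step()], but the applied stress rises linearly from 0 to
#' `sigma0` over `t_ramp` and is then held. Obtained by Duhamel superposition
#' of the step solution over the ramp:
#' for `t <= t_ramp`,
#' \deqn{\varepsilon(t) = \frac{\sigma_0}{H_A t_r}\Big[t - 2\sum_n
#'   \frac{1 - e^{-\lambda_n t}}{M_n^2 \lambda_n}\Big]}
#' and for `t > t_ramp`,
#' \deqn{\varepsilon(t) = \frac{\sigma_0}{H_A}\Big[1 - \frac{2}{t_r}\sum_n
#'   \frac{e^{-\lambda_n (t - t_r)} - e^{-\lambda_n t}}{M_n^2
#'   \lambda_n}\Big].}
#'
#' @inheritParams creep_strain_step
#' @param t_ramp Ramp duration, s.
#' @return Compressive strain, same length as `t`.
#' @export
creep_strain_ramp <- function(mat, h, sigma0, t_ramp, t,
                              ctl = series_control()) {
  stopifnot(inherits(mat, "biphasic_material"))
  if (!is.finite(t_ramp) || t_ramp <= 0) stop("t_ramp must be > 0")
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  if (!is.finite(sigma0) || sigma0 < 0) stop("sigma0 must be >= 0")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  tau <- gel_time(mat, h)
  # Duhamel: eps = sigma0/(H_A t_r) * [Phi(t) - Phi(t - t_r)] with
  # Phi(t) = tau * phi(t/tau) the integrated unit-step response
  phi_t <- kernel_creep_int(t / tau, ctl)
  phi_lag <- ifelse(t > t_ramp,
                    kernel_creep_int(pmax(t - t_ramp, 0) / tau, ctl), 0)
  pmax((sigma0 * tau / (mat$H_A * t_ramp)) * (phi_t - phi_lag), 0)
}

#' Confined-compression stress relaxation under a ramped displacement
#'
#' Total compressive stress at the loaded (impermeable) face of a confined
#' biphasic layer whose surface strain is ramped linearly from 0 to `eps0`
#' over `t_ramp` and then held. The unit-step stress response for these
#' boundary conditions (drained base, impermeable loaded face) is
#' \deqn{G(t) = H_A\Big[1 + 2\sum_{n\ge 1} e^{-n^2\pi^2\, t\, H_A k /
#'   h^2}\Big],}
#' which is singular at `t = 0+` (fluid is instantaneously trapped); the ramp
#' regularizes it. Stress peaks at the end of the ramp and relaxes
#' monotonically to the drained equilibrium `H_A * eps0`.
#'
#' @inheritParams creep_strain_step
#' @param eps0 Target compressive strain, in `(0, 1)`.
#' @param t_ramp Ramp duration, s.
#' @return Compressive stress, Pa, same length as `t`.
#' @export
relaxation_stress <- function(mat, h, eps0, t_ramp, t,
                              ctl = series_control()) {
  stopifnot(inherits(mat, "biphasic_material"))
  if (!is.finite(eps0) || eps0 <= 0 || eps0 >= 1)
    stop("eps0 must lie in (0, 1)")
  if (!is.finite(t_ramp) || t_ramp <= 0) stop("t_ramp must be > 0")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  tau <- gel_time(mat, h)
  rate <- mat$H_A * eps0 / t_ramp
  # Duhamel: sigma = rate * [F(t) - F(t - t_r)] with F(t) = tau * f(t/tau)
  # the integrated unit-step relaxation response
  f_t <- kernel_relax_int(t / tau, ctl)
  f_lag <- ifelse(t > t_ramp,
                  kernel_relax_int(pmax(t - t_ramp, 0) / tau, ctl), 0)
  rate * tau * (f_t - f_lag)
}
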