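#' Buoyancy weighing record
#'
#' The three weighings used to determine tissue porosity: weight in air
#' (`W_wet`), weight submerged in phosphate-buffered saline (`W_PBS`) and dry
#' weight after lyophilization (`W_dry`). Any consistent unit (mg, g, N) is
#' acceptable since the porosity formula is scale-invariant.
#'
#' @param W_wet Wet weight in air.
#' @param W_PBS Weight submerged in PBS.
#' @param W_dry Dry weight after lyophilization.
#' @param density_ratio Density ratio of PBS to water; default 1.005.
#' @return An object of class `buoyancy_weights`.
#' @export
buoyancy_weights <- function(W_wet, W_PBS, W_dry, density_ratio = 1.005) {
  stopifnot(is.numeric(W_wet), is.numeric(W_PBS), is.numeric(W_dry))
  if (any(!is.finite(c(W_wet, W_PBS, W_dry, density_ratio))))
    stop("weights must be finite")
  if (W_dry < 0) stop("W_dry must be >= 0")
  if (W_wet < W_dry) stop("W_wet must equal or exceed W_dry")
  if (W_wet <= W_PBS) stop("W_wet must exceed W_PBS")
  if (density_ratio <= 0) stop("density_ratio must be > 0")
  structure(list(W_wet = W_wet, W_PBS = W_PBS, W_dry = W_dry,
                 density_ratio = density_ratio),
            class = "buoyancy_weights")
}

#' Porosity (water volume fraction) from buoyancy weighings
#'
#' \deqn{\phi^w = \frac{W_{wet} - W_{dry}}{W_{wet} - W_{PBS}} \cdot
#'   \frac{\rho_{PBS}}{\rho_w}}
#' The density-ratio factor can push valid measurements marginally above 1;
#' results in `(1, 1.005]` are clipped to 1 with a warning, anything outside
#' `[0, 1.005]` is rejected as implausible.
#'
#' @param w A [buoyancy_weights()].
#' @return Porosity in `(0, 1]` (dimensionless fraction).
#' @export
porosity <- function(w) {
  stopifnot(inherits(w, "buoyancy_weights"))
  denom <- w$W_wet - w$W_PBS
  if (denom <= 0) stop("W_wet - W_PBS must be positive")
  phi <- (w$W_wet - w$W_dry) / denom * w$density_ratio
  if (phi < 0 || phi > w$density_ratio)
    stop(sprintf("implausible weights: porosity %.4f outside [0, %.3f]",
                 phi, w$density_ratio))
  if (phi > 1) {
    warning(sprintf("porosity %.4f > 1 clipped to 1 (density-ratio factor)",
                    phi))
    phi <- 1
  }
  phi
}

#' Solid volume fraction
#'
#' Complement of the water volume fraction, `phi_s = 1 - phi_w`; this is the
#' reference solid fraction used by the finite element material model.
#'
#' @param phi_w Porosity, in `[0, 1]` (vectorized).
#' @return Solid volume fraction in `[0, 1]`.
#' @export
solid_fraction <- function(phi_w) {
  if (any(!is.finite(phi_w)) || any(phi_w < 0) || any(phi_w > 1))
    stop("phi_w must lie in [0, 1]")
  1 - phi_w
}
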