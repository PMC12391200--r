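#' Classical biphasic unconfined-compression solution
#'
#' Reaction stress of a biphasic cylindrical disk of radius `a` compressed
#' axially between impermeable frictionless platens with a free-draining
#' lateral surface. For a step axial strain `eps0` the classical series
#' solution gives the mean axial (reaction) stress
#' \deqn{\sigma(t) = \varepsilon_0 E \Big[1 + \sum_n A_n
#'   \exp(-\alpha_n^2\, H_A k\, t / a^2)\Big]}
#' with amplitudes
#' \deqn{A_n = \frac{(1-\nu)(1-2\nu)}{(1+\nu)\,[\alpha_n^2 (1-\nu)^2 -
#'   (1-2\nu)]}}
#' and \eqn{\alpha_n} the positive roots of
#' \eqn{J_1(x) - (1-\nu)\, x\, J_0(x)/(1-2\nu) = 0}.
#' The instantaneous response is the incompressible limit `3 E /(2(1+nu))`
#' times `eps0`; the drained equilibrium is `E * eps0`.
#'
#' `unconfined_reaction_ramp()` superposes this solution over a linear
#' strain ramp of duration `t_ramp` (Duhamel), which is the loading used by
#' the disc finite element protocol.
#'
#' @param mat A [biphasic_material()] (uses `H_A`, `k`, `nu`; `E` is derived
#'   via [young_from_aggregate()]).
#' @param a Disk radius, m.
#' @param eps0 Applied axial compressive strain.
#' @param t Time(s), s (vectorized).
#' @param n_roots Number of series roots.
#' @return Mean axial compressive stress, Pa.
#' @export
unconfined_reaction_step <- function(mat, a, eps0, t, n_roots = 60) {
  stopifnot(inherits(mat, "biphasic_material"))
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  E <- young_from_aggregate(mat$H_A, mat$nu)
  ar <- unconfined_roots(mat$nu, n_roots)
  A <- unconfined_amplitudes(mat$nu, ar)
  lam <- ar^2 * mat$H_A * mat$k / a^2
  eps0 * E * (1 + as.numeric(exp(-outer(t, lam)) %*% A))
}

#' @rdname unconfined_reaction_step
#' @param t_ramp Ramp duration, s.
#' @export
unconfined_reaction_ramp <- function(mat, a, eps0, t_ramp, t, n_roots = 60) {
  stopifnot(inherits(mat, "biphasic_material"))
  if (!is.finite(t_ramp) || t_ramp <= 0) stop("t_ramp must be > 0")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  E <- young_from_aggregate(mat$H_A, mat$nu)
  ar <- unconfined_roots(mat$nu, n_roots)
  A <- unconfined_amplitudes(mat$nu, ar)
  lam <- ar^2 * mat$H_A * mat$k / a^2
  # integrated step response: F(t) = t + sum A_n (1 - exp(-lam t)) / lam
  Fint <- function(tt)
    tt + as.numeric((1 - exp(-outer(tt, lam))) %*% (A / lam))
  rate <- eps0 * E / t_ramp
  rate * (Fint(t) - ifelse(t > t_ramp, Fint(pmax(t - t_ramp, 0)), 0))
}

# Positive roots of J1(x) - (1-nu) x J0(x) / (1-2nu) = 0 (excluding x = 0).
unconfined_roots <- function(nu, n_roots) {
  f <- function(x) besselJ(x, 1) - (1 - nu) * x * besselJ(x, 0) / (1 - 2 * nu)
  roots <- numeric(n_roots)
  found <- 0L
  lo <- 1e-6
  step <- 0.05
  x <- lo
  while (found < n_roots) {
    x2 <- x + step
    if (f(x) * f(x2) < 0) {
      found <- found + 1L
      roots[found] <- stats::uniroot(f, c(x, x2), tol = 1e-14)$root
    }
    x <- x2
    if (x > (n_roots + 10) * pi) stop("failed to bracket unconfined roots")
  }
  roots
}

unconfined_amplitudes <- function(nu, roots) {
  (1 - nu) * (1 - 2 * nu) /
    ((1 + nu) * (roots^2 * (1 - nu)^2 - (1 - 2 * nu)))
}
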