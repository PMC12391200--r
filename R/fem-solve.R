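#' Unconfined-compression simulation protocol
#'
#' Ramped axial compression: strain applied linearly over `ramp_duration`
#' and held until `hold_end`. The first time step is `ramp_duration / 200`
#' (suppresses the early-time pressure oscillation of equal-order
#' interpolation) and grows geometrically.
#'
#' @param strain Axial compressive strain (default 0.10).
#' @param ramp_duration Ramp time, s (default 10,000).
#' @param hold_end End of the hold, s (default 400,000).
#' @param max_ramp_step Cap on the step during the ramp, s.
#' @return An object of class `fem_protocol`.
#' @export
fem_protocol <- function(strain = 0.10, ramp_duration = 1e4,
                         hold_end = 4e5,
                         max_ramp_step = ramp_duration / 8) {
  stopifnot(strain > 0, strain < 1, ramp_duration > 0,
            hold_end >= ramp_duration)
  structure(list(strain = strain, ramp_duration = ramp_duration,
                 hold_end = hold_end,
                 max_ramp_step = max_ramp_step),
            class = "fem_protocol")
}

fem_time_grid <- function(protocol) {
  # doubling step levels, 4 steps per level: quantized sizes let the sparse
  # factorization be reused across steps sharing a dt; the hold step is
  # capped at hold_end / 20 because backward Euler damps the slow
  # pressure-decay modes too weakly if the step grows unboundedly
  phase <- function(t0, t1, dt0, dt_cap) {
    out <- numeric(0)
    t <- t0; dt <- dt0; n_lv <- 0L
    while (t < t1 - 1e-9) {
      t <- min(t + dt, t1)
      out <- c(out, t)
      n_lv <- n_lv + 1L
      if (n_lv %% 4L == 0L) dt <- min(dt * 2, dt_cap)
    }
    out
  }
  ramp <- phase(0, protocol$ramp_duration, protocol$ramp_duration / 200,
                protocol$max_ramp_step)
  hold <- phase(protocol$ramp_duration, protocol$hold_end,
                protocol$ramp_duration / 50, protocol$hold_end / 20)
  c(ramp, hold)
}

#' Material table of the three-region disc model
#'
#' Regional biphasic materials used by the disc simulation: aggregate
#' moduli and permeabilities from the confined-compression measurements,
#' a common Poisson ratio of 0.2, porosities complementing the solid
#' fractions, and regional fixed charge densities for the swelling variant.
#'
#' @return Named list of [biphasic_material()] (`NP`, `AF`, `CEP`).
#' @export
default_disc_materials <- function() {
  list(
    NP = biphasic_material(0.44e6, 2.96e-16, nu = 0.2, phi_w0 = 0.873,
                           c_F0 = 182.2),
    AF = biphasic_material(0.57e6, 2.75e-16, nu = 0.2, phi_w0 = 0.817,
                           c_F0 = 135.5),
    CEP = biphasic_material(1.19e6, 1.93e-16, nu = 0.2, phi_w0 = 0.693,
                            c_F0 = 286.7))
}

# per-element property vectors from the region -> material map
fem_props <- function(mesh, materials) {
  regs <- unique(mesh$region)
  if (!all(regs %in% names(materials)))
    stop("materials must be provided for regions: ",
         paste(regs, collapse = ", "))
  E <- nu <- k <- cF0 <- phiw <- numeric(nrow(mesh$elems))
  for (r in regs) {
    m <- materials[[r]]
    stopifnot(inherits(m, "biphasic_material"))
    sel <- mesh$region == r
    E[sel] <- young_from_aggregate(m$H_A, m$nu)
    nu[sel] <- m$nu
    k[sel] <- m$k
    cF0[sel] <- m$c_F0
    phiw[sel] <- m$phi_w0
  }
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  list(lambda = lambda, mu = mu, k = k, E = E, nu = nu,
       c_F0 = cF0, phi_w0 = phiw)
}

# osmotic pressure and tangent per Gauss point from the volumetric strain
osmotic_terms <- function(tr_eps, cF0_gp, phiw_gp, env) {
  J <- 1 + tr_eps
  Jw <- J - 1 + phiw_gp
  bad <- Jw <= 0.05 * phiw_gp
  Jw[bad] <- 0.05 * phiw_gp[bad]  # guard against pore collapse in iterates
  cF <- cF0_gp * phiw_gp / Jw
  RT <- env$R * env$temperature
  root <- sqrt(cF^2 + 4 * env$c_star^2)
  pi_gp <- RT * (root - 2 * env$c_star)
  dpi_dJ <- -RT * cF^2 / (root * Jw)
  list(pi = pi_gp, dpi_dJ = dpi_dJ)
}

#' Quasi-static biphasic finite element solve
#'
#' Mixed displacement-pressure solution of the ramped unconfined compression
#' of a disc (or cylinder) mesh. Backward Euler in time; equal-order
#' trilinear interpolation with a small first step. Boundary conditions:
#' prescribed axial displacement on the top face (frictionless in plane),
#' axially fixed bottom face (frictionless, rigid modes pinned), zero pore
#' pressure on the `drained` node set, symmetry plane (if any) fixed
#' laterally and impermeable.
#'
#' With `swelling = TRUE`, an ideal Donnan osmotic stress `-pi(J) I` with
#' deformation-dependent fixed charge density is added to the solid stress;
#' a free-swelling equilibration is solved first and the compression ramp is
#' applied relative to the swollen state. Each time step is then a Newton
#' iteration on the osmotic nonlinearity.
#'
#' @param mesh An `fe_mesh` from [build_disc_mesh()] or
#'   [build_cylinder_mesh()].
#' @param materials Named list of [biphasic_material()] per region.
#' @param protocol A [fem_protocol()].
#' @param swelling Enable the Donnan swelling contribution.
#' @param env An [ion_environment()] (used when `swelling = TRUE`).
#' @param output_times Times at which fields are stored (defaults to a
#'   spread over the grid including end of ramp and final time).
#' @param verbose Print step progress.
#' @return An object of class `fe_result`: `times` (stored), `U` (list of
#'   n x 3 displacement matrices, m), `P` (list of nodal pressures, Pa),
#'   `stress` (list of ne x 6 effective-stress matrices, Pa, order xx yy zz
#'   xy yz zx), `flux` (list of ne x 3 Darcy flux, m/s), `strain_lagrange`
#'   (list of ne x 2: A-P and I-S components), `reaction` (axial force on
#'   the top face at every time step, N), `step_times`, `oscillation`
#'   (pressure checkerboard metric), `swollen_state` (pre-equilibration
#'   displacement, if swelling).
#' @export
solve_biphasic_fem <- function(mesh, materials, protocol = fem_protocol(),
                               swelling = FALSE, env = ion_environment(),
                               output_times = NULL, verbose = FALSE) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(protocol, "fem_protocol"))
  pre <- fem_precompute(mesh)
  if (any(pre$detJ <= 0)) stop("meshing error: non-positive element Jacobian")
  props <- fem_props(mesh, materials)
  asm <- fem_assemble(mesh, pre, props)
  nn <- nrow(mesh$nodes)
  ndof_u <- 3L * nn
  ndof <- ndof_u + nn

  # Gauss-point copies of swelling properties
  cF0_gp <- rep(props$c_F0, each = 8L)
  phiw_gp <- rep(props$phi_w0, each = 8L)
  use_osm <- swelling && any(cF0_gp > 0)

  # ---- boundary conditions -------------------------------------------------
  top <- mesh$sets$top; bottom <- mesh$sets$bottom
  uz_top_dofs <- 3L * (top - 1L) + 3L
  fixed_u <- c(3L * (bottom - 1L) + 3L)               # bottom u_z
  if (length(mesh$sets$symmetry))
    fixed_u <- c(fixed_u, 3L * (mesh$sets$symmetry - 1L) + 1L)  # u_x = 0
  # pin rigid modes on the bottom face
  pin <- bottom[which.min(rowSums(abs(mesh$nodes[bottom, 1:2, drop = FALSE])))]
  fixed_u <- c(fixed_u, 3L * (pin - 1L) + 2L)          # u_y
  if (length(mesh$sets$symmetry) == 0L) {
    fixed_u <- c(fixed_u, 3L * (pin - 1L) + 1L)        # u_x (no symmetry)
    xmax <- bottom[which.max(mesh$nodes[bottom, 1])]
    fixed_u <- c(fixed_u, 3L * (xmax - 1L) + 2L)       # rotation about z
  }
  fixed_u <- sort(unique(c(fixed_u, uz_top_dofs)))
  fixed_p <- ndof_u + mesh$sets$drained
  fixed <- c(fixed_u, fixed_p)
  free <- setdiff(seq_len(ndof), fixed)

  height <- mesh$height
  x_full <- numeric(ndof)

  # block equilibration: pressure columns scaled by P0 and continuity rows
  # by gam (both E_ref / L_ref) so the saddle-point factorization is
  # well-conditioned despite k being ~20 orders below E
  E_ref <- max(props$lambda + 2 * props$mu)
  L_ref <- mean(rowSums(pre$wdet))^(1 / 3)
  P0 <- E_ref / L_ref
  gam <- E_ref / L_ref

  # ---- free-swelling pre-equilibration ------------------------------------
  u_swell <- numeric(ndof_u)
  if (use_osm) {
    fix_sw <- setdiff(fixed_u, uz_top_dofs)  # top free during swelling
    free_sw <- setdiff(seq_len(ndof_u), fix_sw)
    u <- numeric(ndof_u)
    for (it in 1:50) {
      tr_eps <- as.numeric(Matrix::crossprod(asm$G0, u)) / asm$sqrt_wdet
      os <- osmotic_terms(tr_eps, cF0_gp, phiw_gp, env)
      f_osm <- as.numeric(asm$G0 %*% (os$pi * asm$sqrt_wdet))
      res <- as.numeric(asm$K %*% u) - f_osm
      if (sqrt(sum(res[free_sw]^2)) <
          1e-9 * max(1, sqrt(sum(f_osm^2)))) break
      Kt <- asm$K + asm$G0 %*% Matrix::Diagonal(x = -os$dpi_dJ) %*%
        Matrix::t(asm$G0)
      du <- Matrix::solve(Kt[free_sw, free_sw], -res[free_sw])
      u[free_sw] <- u[free_sw] + as.numeric(du)
    }
    u_swell <- u
    x_full[seq_len(ndof_u)] <- u_swell
  }

  # ---- transient ----------------------------------------------------------
  step_times <- fem_time_grid(protocol)
  if (is.null(output_times)) {
    idx <- unique(round(seq(1, length(step_times),
                            length.out = min(12, length(step_times)))))
    output_times <- step_times[idx]
    te_ramp <- protocol$ramp_duration
    output_times <- sort(unique(c(output_times,
      step_times[which.min(abs(step_times - te_ramp))])))
  }

  ramp_frac <- function(t) min(t / protocol$ramp_duration, 1)
  u_prev <- x_full[seq_len(ndof_u)]
  store <- list(times = numeric(0), U = list(), P = list(), stress = list(),
                flux = list(), strain_lagrange = list())
  reaction <- numeric(length(step_times))
  osc_max <- 0
  t_prev <- 0
  fac <- NULL; fac_dt <- NA_real_
  A <- NULL
  for (s in seq_along(step_times)) {
    t_new <- step_times[s]
    dt <- t_new - t_prev
    # Dirichlet values
    x_full[fixed_p - 0L] <- 0
    x_full[uz_top_dofs] <- u_swell[uz_top_dofs] -
      protocol$strain * height * ramp_frac(t_new)
    # scaled system matrix for this dt (linear part)
    if (is.null(fac) || abs(dt - fac_dt) > 1e-9 * dt) {
      A <- rbind(
        cbind(asm$K, -P0 * asm$Q),
        cbind(gam * Matrix::t(asm$Q), gam * P0 * dt * asm$H))
      A <- methods::as(A, "CsparseMatrix")
      if (!use_osm) fac <- Matrix::lu(A[free, free])
      fac_dt <- dt
    }
    rhs_cont <- as.numeric(Matrix::crossprod(asm$Q, u_prev))
    max_newton <- if (use_osm) 25L else 1L
    for (it in seq_len(max_newton)) {
      u_cur <- x_full[seq_len(ndof_u)]
      p_cur <- x_full[ndof_u + seq_len(nn)]
      if (use_osm) {
        tr_eps <- as.numeric(Matrix::crossprod(asm$G0, u_cur)) /
          asm$sqrt_wdet
        os <- osmotic_terms(tr_eps, cF0_gp, phiw_gp, env)
        f_osm <- as.numeric(asm$G0 %*% (os$pi * asm$sqrt_wdet))
      } else f_osm <- numeric(ndof_u)
      res_u <- as.numeric(asm$K %*% u_cur) - as.numeric(asm$Q %*% p_cur) -
        f_osm
      res_p <- as.numeric(Matrix::crossprod(asm$Q, u_cur)) +
        dt * as.numeric(asm$H %*% p_cur) - rhs_cont
      res_s <- c(res_u, gam * res_p)  # row-scaled residual
      rnorm <- sqrt(sum(c(res_u, res_p)[free]^2))
      ref <- max(sqrt(sum(f_osm^2)), sqrt(sum(res_u^2)), 1e-12)
      col_s <- c(rep(1, ndof_u), rep(P0, nn))  # unscale solution columns
      if (!use_osm) {
        # linear: single direct solve for the full increment
        dx <- as.numeric(Matrix::solve(fac, -res_s[free]))
        x_full[free] <- x_full[free] + dx * col_s[free]
        break
      }
      if (rnorm < 1e-8 * ref && it > 1L) break
      Kos <- asm$G0 %*% Matrix::Diagonal(x = -os$dpi_dJ) %*%
        Matrix::t(asm$G0)
      At <- rbind(cbind(asm$K + Kos, -P0 * asm$Q),
                  cbind(gam * Matrix::t(asm$Q), gam * P0 * dt * asm$H))
      dx <- as.numeric(Matrix::solve(At[free, free], -res_s[free]))
      x_full[free] <- x_full[free] + dx * col_s[free]
      if (it == max_newton)
        stop(sprintf("FE Newton did not converge at t = %g s", t_new))
    }
    if (any(!is.finite(x_full)))
      stop(sprintf("FE solver failure at t = %g s (step %d)", t_new, s))
    u_cur <- x_full[seq_len(ndof_u)]
    p_cur <- x_full[ndof_u + seq_len(nn)]
    # reaction on top face: residual of the solid equations at fixed dofs
    if (use_osm) {
      tr_eps <- as.numeric(Matrix::crossprod(asm$G0, u_cur)) / asm$sqrt_wdet
      os <- osmotic_terms(tr_eps, cF0_gp, phiw_gp, env)
      f_osm <- as.numeric(asm$G0 %*% (os$pi * asm$sqrt_wdet))
    } else f_osm <- numeric(ndof_u)
    res_u <- as.numeric(asm$K %*% u_cur) - as.numeric(asm$Q %*% p_cur) - f_osm
    reaction[s] <- -sum(res_u[uz_top_dofs])
    # pressure oscillation metric: worst within-element nodal range / global
    p_rng <- diff(range(p_cur))
    if (p_rng > 0) {
      pe <- matrix(p_cur[mesh$elems], ncol = 8)
      osc <- max(apply(pe, 1, function(v) diff(range(v)))) / p_rng
      osc_max <- max(osc_max, osc)
    }
    if (any(abs(output_times - t_new) < 1e-9 * max(t_new, 1))) {
      fields <- fem_recover_fields(mesh, pre, asm, props, u_cur, p_cur,
                                   if (use_osm) os$pi else NULL)
      store$times <- c(store$times, t_new)
      store$U <- c(store$U, list(matrix(u_cur, ncol = 3, byrow = TRUE)))
      store$P <- c(store$P, list(p_cur))
      store$stress <- c(store$stress, list(fields$stress))
      store$flux <- c(store$flux, list(fields$flux))
      store$strain_lagrange <- c(store$strain_lagrange,
                                 list(fields$strain_lagrange))
    }
    if (verbose)
      message(sprintf("t = %8.0f s  reaction = %.4g N", t_new, reaction[s]))
    u_prev <- u_cur
    t_prev <- t_new
  }

  structure(list(times = store$times, U = store$U, P = store$P,
                 stress = store$stress, flux = store$flux,
                 strain_lagrange = store$strain_lagrange,
                 reaction = reaction, step_times = step_times,
                 oscillation = osc_max, region = mesh$region, mesh = mesh,
                 swelling = swelling,
                 swollen_state = if (use_osm)
                   matrix(u_swell, ncol = 3, byrow = TRUE) else NULL),
            class = "fe_result")
}

# element-averaged effective stress, Darcy flux and Lagrange strain
fem_recover_fields <- function(mesh, pre, asm, props, u, p, pi_gp = NULL) {
  elems <- mesh$elems
  ne <- nrow(elems)
  Ue <- array(0, c(ne, 8, 3))
  peN <- matrix(p[elems], ncol = 8)
  for (a in 1:8) Ue[, a, ] <- matrix(u[3L * (elems[, a] - 1L) +
                                         rep(1:3, each = ne)], ncol = 3)
  grad <- array(0, c(ne, 3, 3))   # mean over gp of du_i/dx_j
  gp_vol <- rowSums(pre$wdet)
  gradp <- matrix(0, ne, 3)
  for (q in 1:8) {
    dd <- pre$dNdx[[q]]
    w <- pre$wdet[, q]
    for (i in 1:3) for (j in 1:3)
      grad[, i, j] <- grad[, i, j] +
        w * rowSums(Ue[, , i] * dd[, , j])
    for (j in 1:3)
      gradp[, j] <- gradp[, j] + w * rowSums(peN * dd[, , j])
  }
  grad <- grad / array(gp_vol, c(ne, 3, 3))
  gradp <- gradp / gp_vol
  eps <- array(0, c(ne, 3, 3))
  for (i in 1:3) for (j in 1:3)
    eps[, i, j] <- 0.5 * (grad[, i, j] + grad[, j, i])
  tr <- eps[, 1, 1] + eps[, 2, 2] + eps[, 3, 3]
  pi_el <- if (is.null(pi_gp)) 0 else
    rowMeans(matrix(pi_gp, ncol = 8, byrow = TRUE))
  stress <- cbind(
    xx = props$lambda * tr + 2 * props$mu * eps[, 1, 1] - pi_el,
    yy = props$lambda * tr + 2 * props$mu * eps[, 2, 2] - pi_el,
    zz = props$lambda * tr + 2 * props$mu * eps[, 3, 3] - pi_el,
    xy = 2 * props$mu * eps[, 1, 2],
    yz = 2 * props$mu * eps[, 2, 3],
    zx = 2 * props$mu * eps[, 3, 1])
  flux <- -props$k * gradp
  # Lagrange strain E = eps + 0.5 grad^T grad (A-P is y, I-S is z)
  E_ap <- eps[, 2, 2] + 0.5 * (grad[, 1, 2]^2 + grad[, 2, 2]^2 +
                                 grad[, 3, 2]^2)
  E_is <- eps[, 3, 3] + 0.5 * (grad[, 1, 3]^2 + grad[, 2, 3]^2 +
                                 grad[, 3, 3]^2)
  list(stress = stress, flux = flux,
       strain_lagrange = cbind(AP = E_ap, IS = E_is))
}
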