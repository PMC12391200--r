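#' Finite-difference grid for 1-D consolidation
#'
#' @param n_z Number of spatial nodes across the layer (>= 11).
#' @param dt Time step, s.
#' @param t_end Final time, s.
#' @param theta Implicitness weight in `[0.5, 1]`; 1 is backward Euler,
#'   0.5 Crank-Nicolson.
#' @return An object of class `grid1d`.
#' @export
grid1d <- function(n_z = 201L, dt, t_end, theta = 1) {
  if (n_z < 11) stop("n_z must be >= 11")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.finite(theta) || theta < 0.5 || theta > 1)
    stop("theta must lie in [0.5, 1]")
  structure(list(n_z = as.integer(n_z), dt = dt, t_end = t_end,
                 theta = theta), class = "grid1d")
}

#' Piecewise-linear load or displacement history
#'
#' @param kind `"stress_control"` (values are applied compressive stress, Pa)
#'   or `"displacement_control"` (values are applied surface compressive
#'   strain, dimensionless).
#' @param times Breakpoint times, s; strictly increasing, starting at 0.
#' @param values Values at the breakpoints; linearly interpolated between
#'   them and held constant after the last breakpoint.
#' @return An object of class `load_history` with an `interp(t)` evaluator.
#' @export
load_history <- function(kind = c("stress_control", "displacement_control"),
                         times, values) {
  kind <- match.arg(kind)
  if (length(times) != length(values) || length(times) < 1L)
    stop("times and values must have equal positive length")
  if (times[1] != 0) stop("history must start at t = 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  f <- if (length(times) == 1L) {
    v <- values
    function(t) rep(v, length(t))
  } else stats::approxfun(times, values, rule = 2)
  structure(list(kind = kind, times = times, values = values, interp = f),
            class = "load_history")
}

#' Solve 1-D biphasic consolidation by finite differences
#'
#' Theta-scheme finite-difference solution of the confined-compression
#' consolidation equation `de/dt = c d2e/dz2` with `c = H_A k`, where `e(z,t)`
#' is the local compressive strain. Boundary conditions reflect the standard
#' test chamber: the base `z = 0` drains freely through a porous platen
#' (pore pressure `p = 0`, so `e(0,t) = sigma(t)/H_A`), while the loaded face
#' `z = h` is impermeable (`de/dz = 0`). Total compressive stress
#' `sigma = H_A e + p` is uniform through the thickness (quasi-static
#' equilibrium).
#'
#' Under stress control `sigma(t)` is prescribed; under displacement control
#' the surface strain (mean of `e`) is prescribed and the uniform reaction
#' stress is recovered as the extra unknown via superposition of two solves
#' against the same factorized operator.
#'
#' @param mat A [biphasic_material()].
#' @param h Layer thickness, m.
#' @param history A [load_history()].
#' @param grid A [grid1d()].
#' @return A list of class `consolidation_solution` with elements `t`,
#'   `surface_displacement` (m, compressive), `reaction_stress` (Pa),
#'   `strain` (matrix n_t x n_z of local strain), `pressure` (matrix,
#'   Pa), `z` (node coordinates), and the discrete fluid balance diagnostics
#'   `outflow_cum` and `dilatation` (both in m, equal up to round-off).
#' @export
solve_consolidation <- function(mat, h, history, grid) {
  stopifnot(inherits(mat, "biphasic_material"),
            inherits(history, "load_history"), inherits(grid, "grid1d"))
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  dt <- grid$dt
  th <- grid$theta
  c0 <- mat$H_A * mat$k
  # spatial mesh: n_z-node uniform grid, refined geometrically towards the
  # drained face z = 0 so that the diffusion boundary layer sqrt(c0 * dt_sub)
  # of the smallest substep stays resolved (singular transients after load
  # kinks live there)
  dz_u <- h / (grid$n_z - 1)
  d_min <- max(sqrt(c0 * dt) / 64, dz_u / 4096)
  if (d_min < dz_u / 2) {
    sp <- d_min * 2^(seq(0, log2(dz_u / d_min), by = 0.25))
    sp <- sp[cumsum(sp) < 8 * dz_u]
  } else sp <- numeric(0)
  rest <- h - sum(sp)
  n_u <- max(2L, round(rest / dz_u))
  z <- c(0, cumsum(c(sp, rep(rest / n_u, n_u))))
  z[length(z)] <- h
  n <- length(z)
  d <- diff(z)  # cell spacings, length n - 1
  nt <- ceiling(grid$t_end / dt - 1e-9)
  out_times <- c(0, seq_len(nt) * dt)
  if (out_times[nt + 1] > grid$t_end + 1e-9 * dt)
    out_times[nt + 1] <- grid$t_end
  # geometric substepping after every history breakpoint (including t = 0):
  # local steps grow from dt/256 up to dt over a span of 8*dt, resolving the
  # singular transients that step loads and ramp kinks excite; outputs stay
  # on the uniform grid
  offsets <- dt * 2^seq(-10, 3, by = 0.25)
  kinks <- unique(c(0, history$times))
  graded <- unlist(lapply(kinks, function(tb) tb + offsets))
  graded <- graded[graded > 0 & graded < grid$t_end]
  # drop graded points that collide with an output time (outputs win)
  near_out <- vapply(graded,
                     function(x) min(abs(x - out_times)) < 1e-8 * dt,
                     logical(1))
  step_times <- sort(unique(c(0, out_times[-1], graded[!near_out])))

  # variable-spacing discrete Laplacian L (Dirichlet row 1, mirrored-Neumann
  # row n): (Le)_i = 2/(d_{i-1}+d_i) [ (e_{i+1}-e_i)/d_i - (e_i-e_{i-1})/d_{i-1} ]
  i_int <- 2:(n - 1)
  dm <- d[i_int - 1]; dp <- d[i_int]
  lo <- c(2 / (dm * (dm + dp)), 2 / d[n - 1]^2)           # sub-diagonal, rows 2..n
  di <- c(0, -2 / (dm * dp), -2 / d[n - 1]^2)             # diagonal
  up <- c(0, 2 / (dp * (dm + dp)))                        # super-diagonal, rows 2..n-1
  L <- Matrix::bandSparse(n, n, k = -1:1, diagonals = list(lo, di, up))
  make_ops <- function(dti) {
    A <- Matrix::Diagonal(n) - th * c0 * dti * L
    A[1, ] <- 0
    A[1, 1] <- 1
    A <- methods::as(A, "CsparseMatrix")
    list(fac = Matrix::lu(A),
         B = Matrix::Diagonal(n) + (1 - th) * c0 * dti * L)
  }
  wq <- c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)  # trapezoid weights

  disp_ctrl <- history$kind == "displacement_control"

  e <- numeric(n)
  n_out <- length(out_times)
  sig <- numeric(n_out)
  strain <- matrix(0, n_out, n)
  outflow <- numeric(n_out)
  sig[1] <- if (disp_ctrl) 0 else history$interp(0)
  # recorded t = 0 state is the undeformed layer; the boundary-node jump of a
  # step load has zero measure and is imposed through the Dirichlet row from
  # the first substep on
  strain[1, ] <- 0
  cum_q <- 0
  ops <- NULL; ops_dt <- NA_real_; e_b <- NULL; mean_b <- NA_real_
  i_out <- 1L
  for (i in seq_len(length(step_times) - 1L)) {
    tn1 <- step_times[i + 1]
    dti <- tn1 - step_times[i]
    if (is.null(ops) || abs(dti - ops_dt) > 1e-9 * dt) {
      ops <- make_ops(dti)
      ops_dt <- dti
      if (disp_ctrl) {
        rhs_b <- numeric(n); rhs_b[1] <- 1 / mat$H_A
        e_b <- as.numeric(Matrix::solve(ops$fac, rhs_b))
        mean_b <- sum(wq * e_b) / h
      }
    }
    b <- as.numeric(ops$B %*% e)
    if (!disp_ctrl) {
      s1 <- history$interp(tn1)
      b[1] <- s1 / mat$H_A
      e_new <- as.numeric(Matrix::solve(ops$fac, b))
    } else {
      b[1] <- 0
      e_a <- as.numeric(Matrix::solve(ops$fac, b))
      target <- history$interp(tn1) * h  # prescribed surface displacement
      s1 <- (target - sum(wq * e_a)) / (mean_b * h)
      e_new <- e_a + s1 * e_b
    }
    if (any(!is.finite(e_new)))
      stop(sprintf("consolidation solver failure at step %d (t = %g s)",
                   i, tn1))
    # discrete boundary outflow (telescoped form of the scheme); theta-weighted
    flux_old <- c0 * (e[1] - e[2]) / d[1]
    flux_new <- c0 * (e_new[1] - e_new[2]) / d[1]
    cum_q <- cum_q + dti * (th * flux_new + (1 - th) * flux_old)
    e <- e_new
    if (abs(tn1 - out_times[i_out + 1L]) < 1e-9 * dt) {
      i_out <- i_out + 1L
      sig[i_out] <- s1
      strain[i_out, ] <- e
      outflow[i_out] <- cum_q
    }
  }
  surf <- as.numeric(strain %*% wq)
  press <- sweep(-strain * mat$H_A, 1, sig, "+")  # p = sigma - H_A e
  # discrete dilatation measure matched to the telescoped flux (excludes the
  # Dirichlet node, half-weights the far node)
  wd <- c(0, wq[-1])
  dil <- as.numeric(strain %*% wd)
  structure(list(t = out_times, surface_displacement = surf,
                 reaction_stress = sig, strain = strain, pressure = press,
                 z = z,
                 outflow_cum = outflow, dilatation = dil - dil[1]),
            class = "consolidation_solution")
}

#' Default oracle grid for a given material and history
#'
#' Chooses `dt = min(tau/2000, ramp/50)` and 201 nodes with Crank-Nicolson
#' time stepping (`theta = 0.5`; the geometric substepping after history
#' kinks suppresses the oscillations Crank-Nicolson is otherwise prone to).
#' At this resolution the finite-difference solution is well inside the 1e-3
#' comparison tolerance against the series solutions.
#'
#' @param mat A [biphasic_material()].
#' @param h Layer thickness, m.
#' @param t_end Final time, s.
#' @param ramp_duration Shortest ramp in the history, s (caps the step).
#' @param theta Implicitness weight.
#' @return A [grid1d()].
#' @export
oracle_grid <- function(mat, h, t_end, ramp_duration = Inf, theta = 0.5) {
  tau <- gel_time(mat, h)
  dt <- min(tau / 2000, ramp_duration / 50, t_end / 50)
  # resolve the diffusion boundary layer sqrt(c * dt) present at the first
  # output time with >= 4 cells (matters when t_end << tau)
  n_z <- max(201, 4 * ceiling(sqrt(tau / dt)))
  n_z <- min(n_z, 2001)
  grid1d(n_z, dt = dt, t_end = t_end, theta = theta)
}

#' Observed order of accuracy of the consolidation solver
#'
#' Richardson-style self-convergence: solves the same problem on a list of
#' nested grids and estimates the observed order from errors against the
#' finest grid (which is excluded from the fit).
#'
#' @param mat A [biphasic_material()].
#' @param h Layer thickness, m.
#' @param history A [load_history()].
#' @param grids List of at least 3 [grid1d()] objects, coarse to fine.
#' @param probe_time Time at which surface displacement errors are measured;
#'   defaults to the final time of the coarsest grid.
#' @return A list with `errors`, `h_eff` (spacing proxies) and `order`
#'   (log-log slope).
#' @export
convergence_study <- function(mat, h, history, grids, probe_time = NULL) {
  if (length(grids) < 3) stop("need >= 3 grids")
  if (is.null(probe_time)) probe_time <- grids[[1]]$t_end
  vals <- vapply(grids, function(g) {
    sol <- solve_consolidation(mat, h, history, g)
    stats::approx(sol$t, sol$surface_displacement, xout = probe_time)$y
  }, numeric(1))
  ref <- vals[length(vals)]
  errs <- abs(vals[-length(vals)] - ref)
  hs <- vapply(grids[-length(grids)], function(g) 1 / (g$n_z - 1), numeric(1))
  # if spatial spacing constant, fall back to dt as the refinement variable
  if (diff(range(hs)) < 1e-15)
    hs <- vapply(grids[-length(grids)], function(g) g$dt, numeric(1))
  ord <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
  list(errors = errs, h_eff = hs, order = unname(ord))
}
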