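#' Creep-phase displacement trace
#'
#' Time-stamped displacement record of the creep phase of a confined
#' compression test, expressed relative to the post-relaxation equilibrium
#' state. Internally SI (s, m, N); use [read_creep_trace()] for instrument
#' files in um / mN convention.
#'
#' @param time Sample times, s; strictly increasing, starting at 0.
#' @param displacement Creep displacement, m (compressive positive).
#' @param applied_load Target creep load, N (scalar).
#' @param specimen A [specimen_geometry()].
#' @param region Region label: `"NP"`, `"AF"` or `"CEP"`.
#' @param specimen_id,donor_id,disc_level Identifying labels.
#' @param equilibrium_load Relaxation equilibrium load, N (used for swelling
#'   pressure); optional.
#' @return An object of class `creep_trace`.
#' @export
creep_trace <- function(time, displacement, applied_load, specimen,
                        region = c("NP", "AF", "CEP"),
                        specimen_id = "specimen", donor_id = NA,
                        disc_level = NA, equilibrium_load = NA_real_) {
  region <- match.arg(region)
  stopifnot(inherits(specimen, "specimen_geometry"),
            length(time) == length(displacement))
  if (length(time) < 2L) stop("trace needs at least two samples")
  if (time[1] != 0 || any(diff(time) <= 0))
    stop("time must be strictly increasing from 0")
  if (any(!is.finite(displacement))) stop("displacement must be finite")
  if (any(abs(displacement) >= specimen$thickness))
    stop("displacement exceeds specimen thickness")
  if (!is.finite(applied_load) || applied_load < 0)
    stop("applied_load must be a non-negative scalar")
  structure(list(time = time, displacement = displacement,
                 applied_load = applied_load, specimen = specimen,
                 region = region, specimen_id = specimen_id,
                 donor_id = donor_id, disc_level = disc_level,
                 equilibrium_load = equilibrium_load),
            class = "creep_trace")
}

#' Swelling pressure from the relaxation equilibrium load
#'
#' The equilibrium load recorded at the end of the stress-relaxation phase
#' divided by the specimen cross-sectional area (19.63 mm^2 for the standard
#' 5 mm diameter).
#'
#' @param equilibrium_load Equilibrium load, N.
#' @param area Cross-sectional area, m^2.
#' @return Swelling pressure, Pa.
#' @export
swelling_pressure <- function(equilibrium_load, area) {
  if (any(!is.finite(area)) || any(area <= 0)) stop("area must be > 0")
  if (any(!is.finite(equilibrium_load)) || any(equilibrium_load < 0))
    stop("equilibrium_load must be >= 0")
  equilibrium_load / area
}

#' Creep load from the relaxation equilibrium load
#'
#' @param equilibrium_load Equilibrium load, N.
#' @param fraction Creep load fraction (default protocol value 0.20).
#' @return Creep load, N.
#' @export
creep_load <- function(equilibrium_load, fraction = 0.20) {
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1))
    stop("fraction must lie in (0, 1)")
  equilibrium_load * fraction
}

# dimensionless time at which the unit-step creep response reaches
# 0.5 / 1.05 of equilibrium (used by the half-time initializer)
half_time_x <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ctl <- series_control()
      cache <<- stats::uniroot(
        function(x) kernel_creep_step(x, ctl) - 0.5 / 1.05,
        c(1e-4, 20), tol = 1e-12)$root
    }
    cache
  }
})

#' Initial parameter guess for the creep fit
#'
#' `H_A0` is the applied stress over the final observed strain inflated by 5%
#' (a cheap equilibrium proxy); `k0` follows from numerically inverting the
#' step creep solution at the time the trace reaches half its final
#' displacement.
#'
#' @param trace A [creep_trace()].
#' @param protocol A [load_protocol()].
#' @return Named list `H_A0` (Pa), `k0` (m^4/N/s).
#' @export
initialize_fit <- function(trace, protocol = load_protocol()) {
  stopifnot(inherits(trace, "creep_trace"))
  h <- trace$specimen$thickness
  sigma0 <- trace$applied_load / trace$specimen$area
  d_end <- trace$displacement[length(trace$displacement)]
  eps_end <- d_end / h
  if (eps_end <= 0) stop("degenerate trace: final strain is not positive")
  H_A0 <- sigma0 / (1.05 * eps_end)
  t_half <- trace$time[which(trace$displacement >= 0.5 * d_end)[1]]
  if (is.na(t_half) || t_half <= 0) t_half <- trace$time[2]
  tau0 <- t_half / half_time_x()
  k0 <- h^2 / (H_A0 * tau0)
  list(H_A0 = H_A0, k0 = k0)
}

#' Fit the linear biphasic model to a creep trace
#'
#' Nonlinear least squares on the creep displacement using the ramped
#' (Duhamel) confined-compression solution, with the aggregate modulus and
#' hydraulic permeability as free parameters. Optimization runs in
#' log-parameter space with a Levenberg-Marquardt iteration, which keeps both
#' parameters positive without constraints and copes with the orders of
#' magnitude spanned by permeability.
#'
#' @param trace A [creep_trace()].
#' @param protocol A [load_protocol()] (supplies the ramp duration).
#' @param ctl A [series_control()].
#' @param max_iter Iteration cap; exceeding it yields `converged = FALSE`,
#'   not an error.
#' @return An object of class `fit_result`: estimates `H_A_hat` (Pa) and
#'   `k_hat` (m^4/N/s), `swelling_pressure` (Pa, `NA` if the trace has no
#'   equilibrium load), `r_squared`, `rmse` (m), `n_iter`, `converged`,
#'   `ci_halfwidths` (95%, delta method from the Jacobian), and report-unit
#'   copies `H_A_MPa`, `k_report`.
#' @export
fit_biphasic_creep <- function(trace, protocol = load_protocol(),
                               ctl = series_control(), max_iter = 100L) {
  stopifnot(inherits(trace, "creep_trace"), inherits(protocol, "load_protocol"))
  n_obs <- length(trace$time)
  if (n_obs < 30L) stop("trace too short: need >= 30 samples")
  # trend check: quantization makes traces locally non-monotone, so reject
  # only a globally flat or negative trend
  if (stats::cor(trace$time, trace$displacement) <= 0 ||
      trace$displacement[n_obs] <= 0)
    stop("data-quality error: creep displacement has no positive trend")

  h <- trace$specimen$thickness
  sigma0 <- trace$applied_load / trace$specimen$area
  t_ramp <- protocol$ramp_duration
  obs <- trace$displacement
  tt <- trace$time

  model <- function(p) {
    m <- biphasic_material(exp(p[1]), exp(p[2]), phi_w0 = 0.8)
    creep_strain_ramp(m, h, sigma0, t_ramp, tt, ctl) * h
  }

  init <- initialize_fit(trace, protocol)
  p <- c(log(init$H_A0), log(init$k0))
  lambda <- 1e-3
  r <- model(p) - obs
  ssr <- sum(r^2)
  n_iter <- 0L
  converged <- FALSE
  J <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # forward-difference Jacobian in log space
    J <- vapply(1:2, function(j) {
      dp <- p; step <- 1e-6
      dp[j] <- dp[j] + step
      (model(dp) - (r + obs)) / step
    }, numeric(n_obs))
    g <- crossprod(J, r)
    H <- crossprod(J)
    repeat {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H)), -g),
        error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      p_new <- p + as.numeric(step)
      r_new <- tryCatch(model(p_new) - obs, error = function(e) NULL)
      ssr_new <- if (is.null(r_new)) Inf else sum(r_new^2)
      if (ssr_new < ssr) {
        lambda <- max(lambda / 3, 1e-12)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (lambda > 1e12) break
    rel_drop <- (ssr - ssr_new) / max(ssr, .Machine$double.eps)
    p <- p_new; r <- r_new; ssr <- ssr_new
    if (sqrt(sum(step^2)) < 1e-10 ||
        (rel_drop < 1e-12 && max(abs(g)) < 1e-8 * sqrt(ssr + 1e-30))) {
      converged <- TRUE
      break
    }
  }

  H_A_hat <- exp(p[1]); k_hat <- exp(p[2])
  rmse <- sqrt(ssr / n_obs)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ssr / ss_tot)) else NA_real_
  # delta-method 95% CI half-widths from the log-space Jacobian
  ci <- c(H_A = NA_real_, k = NA_real_)
  dof <- n_obs - 2L
  cov_log <- tryCatch(solve(crossprod(J)) * ssr / dof,
                      error = function(e) NULL)
  if (!is.null(cov_log)) {
    se_log <- sqrt(pmax(diag(cov_log), 0))
    tq <- stats::qt(0.975, dof)
    ci <- c(H_A = tq * se_log[1] * H_A_hat, k = tq * se_log[2] * k_hat)
  }

  tau_hat <- h^2 / (H_A_hat * k_hat)
  duration_warning <- max(tt) < 0.2 * tau_hat
  if (duration_warning)
    warning(sprintf(
      "trace spans %.2f of the fitted consolidation time; k is weakly identified",
      max(tt) / tau_hat))

  sp <- if (is.finite(trace$equilibrium_load))
    swelling_pressure(trace$equilibrium_load, trace$specimen$area)
  else NA_real_

  structure(list(
    H_A_hat = H_A_hat, k_hat = k_hat, swelling_pressure = sp,
    r_squared = r2, rmse = rmse, n_iter = n_iter, converged = converged,
    ci_halfwidths = ci, tau_hat = tau_hat,
    duration_warning = duration_warning,
    H_A_MPa = H_A_hat / 1e6,
    k_report = permeability_to_report_units(k_hat),
    specimen_id = trace$specimen_id, region = trace$region,
    donor_id = trace$donor_id, disc_level = trace$disc_level),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s)\n", x$specimen_id, x$region))
  cat(sprintf("  H_A = %.3f MPa, k = %.3f x 1e-16 m^4/N/s, R2 = %.5f\n",
              x$H_A_MPa, x$k_hat / 1e-16, x$r_squared))
  cat(sprintf("  converged: %s (%d iterations)\n", x$converged, x$n_iter))
  invisible(x)
}

#' Read an instrument creep trace (CSV + JSON sidecar)
#'
#' CSV columns `time_s, displacement_um, force_mN`; the JSON sidecar holds
#' specimen metadata (`specimen_id`, `region`, `donor_id`, `disc_level`,
#' `thickness_mm`, `diameter_mm`, optionally `equilibrium_load_mN` and
#' `creep_load_mN`). Displacement is stored in um and force in mN
#' (instrument precision convention) and converted to SI on read.
#'
#' @param csv_path Path to the trace CSV.
#' @param json_path Path to the metadata sidecar; defaults to the CSV path
#'   with extension `.json`.
#' @return A [creep_trace()].
#' @export
read_creep_trace <- function(csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  df <- utils::read.csv(csv_path)
  need <- c("time_s", "displacement_um")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns time_s, displacement_um")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  geom <- specimen_geometry(thickness = meta$thickness_mm * 1e-3,
                            diameter = meta$diameter_mm * 1e-3)
  load_N <- if (!is.null(meta$creep_load_mN)) meta$creep_load_mN * 1e-3
            else max(df$force_mN, na.rm = TRUE) * 1e-3
  eq_N <- if (!is.null(meta$equilibrium_load_mN))
    meta$equilibrium_load_mN * 1e-3 else NA_real_
  creep_trace(time = df$time_s, displacement = df$displacement_um * 1e-6,
              applied_load = load_N, specimen = geom, region = meta$region,
              specimen_id = meta$specimen_id, donor_id = meta$donor_id,
              disc_level = meta$disc_level, equilibrium_load = eq_N)
}
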