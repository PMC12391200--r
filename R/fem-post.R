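#' Von Mises (effective) stress
#'
#' Second-deviatoric-invariant scalar of a symmetric stress tensor:
#' \deqn{\sigma_{vM} = \sqrt{\tfrac12[(\sigma_{xx}-\sigma_{yy})^2 +
#'   (\sigma_{yy}-\sigma_{zz})^2 + (\sigma_{zz}-\sigma_{xx})^2] +
#'   3(\sigma_{xy}^2+\sigma_{yz}^2+\sigma_{zx}^2)}.}
#'
#' @param S Numeric matrix with 6 columns (order xx, yy, zz, xy, yz, zx) or
#'   a length-6 vector.
#' @return Vector of von Mises stresses (same units as `S`).
#' @export
von_mises <- function(S) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  stopifnot(ncol(S) == 6)
  sqrt(0.5 * ((S[, 1] - S[, 2])^2 + (S[, 2] - S[, 3])^2 +
                (S[, 3] - S[, 1])^2) +
         3 * (S[, 4]^2 + S[, 5]^2 + S[, 6]^2))
}

#' Darcy fluid flux from a nodal pressure field
#'
#' `w = -k grad(p)`, evaluated as the element-averaged pressure gradient
#' times the regional permeability.
#'
#' @param mesh An `fe_mesh`.
#' @param p Nodal pressure vector, Pa.
#' @param k_by_region Named permeability per region, m^4 N^-1 s^-1 (a single
#'   unnamed value is recycled).
#' @return Matrix (n_elements x 3) of flux components, m/s.
#' @export
fluid_flux <- function(mesh, p, k_by_region) {
  stopifnot(inherits(mesh, "fe_mesh"), length(p) == nrow(mesh$nodes))
  pre <- fem_precompute(mesh)
  ne <- nrow(mesh$elems)
  k_el <- if (is.null(names(k_by_region)))
    rep(k_by_region[1], ne)
  else {
    if (!all(unique(mesh$region) %in% names(k_by_region)))
      stop("k_by_region must cover all regions")
    unname(unlist(k_by_region)[mesh$region])
  }
  peN <- matrix(p[mesh$elems], ncol = 8)
  gradp <- matrix(0, ne, 3)
  for (q in 1:8) {
    dd <- pre$dNdx[[q]]
    w <- pre$wdet[, q]
    for (j in 1:3)
      gradp[, j] <- gradp[, j] + w * rowSums(peN * dd[, , j])
  }
  gradp <- gradp / rowSums(pre$wdet)
  -k_el * gradp
}

#' Region-by-time peak outcome table
#'
#' Maximum magnitudes per region at the requested stored times: effective
#' (von Mises) stress, fluid pressure, fluid flux magnitude, and the
#' anterior-posterior and inferior-superior Lagrange strains (signed values
#' of largest magnitude). Mirrors the layout of peak-outcome summaries used
#' for disc simulations. Units: MPa, kPa, mm/s, dimensionless.
#'
#' @param result An `fe_result` from [solve_biphasic_fem()].
#' @param times Times to include (defaults to all stored); each is matched
#'   to the nearest stored time.
#' @return Data frame with columns `time`, `region`, `stress_MPa`,
#'   `pressure_kPa`, `flux_mm_s`, `strain_AP`, `strain_IS`.
#' @export
peak_table <- function(result, times = NULL) {
  stopifnot(inherits(result, "fe_result"))
  if (is.null(times)) times <- result$times
  rows <- NULL
  elems <- result$mesh$elems
  for (tq in times) {
    i <- which.min(abs(result$times - tq))
    vm <- von_mises(result$stress[[i]])
    fx <- sqrt(rowSums(result$flux[[i]]^2))
    p_el <- matrix(result$P[[i]][elems], ncol = 8)
    sl <- result$strain_lagrange[[i]]
    for (reg in unique(result$region)) {
      sel <- result$region == reg
      pk_sgn <- function(v) v[which.max(abs(v))]
      rows <- rbind(rows, data.frame(
        time = result$times[i], region = reg,
        stress_MPa = max(vm[sel]) / 1e6,
        pressure_kPa = max(abs(p_el[sel, ])) / 1e3,
        flux_mm_s = max(fx[sel]) * 1e3,
        strain_AP = pk_sgn(sl[sel, "AP"]),
        strain_IS = pk_sgn(sl[sel, "IS"]),
        stringsAsFactors = FALSE))
    }
  }
  rows
}

#' Write a legacy-ASCII VTK file of a stored solution time
#'
#' Unstructured-grid output with nodal displacement and pressure and
#' element von Mises stress and flux, viewable in ParaView.
#'
#' @param result An `fe_result`.
#' @param file Output path (`.vtk`).
#' @param time_index Index into `result$times` (default: last stored).
#' @return Invisibly, `file`.
#' @export
write_vtk <- function(result, file, time_index = length(result$times)) {
  stopifnot(inherits(result, "fe_result"))
  mesh <- result$mesh
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("biphasic disc solution t = %g s",
                       result$times[time_index]),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9L), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  writeLines(c(sprintf("POINT_DATA %d", nn),
               "VECTORS displacement double"), con)
  utils::write.table(result$U[[time_index]], con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(result$P[[time_index]]), con)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(von_mises(result$stress[[time_index]])), con)
  writeLines("VECTORS fluid_flux double", con)
  utils::write.table(result$flux[[time_index]], con, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
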