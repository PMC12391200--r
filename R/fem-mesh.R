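#' Idealized cervical disc geometry
#'
#' Parametric half-disc geometry used by the finite element model: a
#' bean-shaped cross section (elliptical footprint with a posterior
#' concavity near the mid-sagittal plane) extruded to the disc height, with
#' cartilaginous endplate layers capping the top and bottom and a
#' posteriorly biased nucleus region occupying a set fraction of the
#' cross-sectional area.
#'
#' @param ap_depth Anterior-posterior depth, mm.
#' @param lat_width Full lateral width, mm.
#' @param disc_height Disc height, mm.
#' @param cep_thickness Endplate layer thickness, mm.
#' @param np_area_fraction Fraction of the cross-section occupied by the NP.
#' @param bean_concavity Posterior-margin concavity shape parameter.
#' @return An object of class `disc_geometry` (lengths stored in mm).
#' @export
disc_geometry <- function(ap_depth = 15, lat_width = 20, disc_height = 6,
                          cep_thickness = 0.9, np_area_fraction = 0.4,
                          bean_concavity = 0.3) {
  if (any(!is.finite(c(ap_depth, lat_width, disc_height, cep_thickness))) ||
      any(c(ap_depth, lat_width, disc_height, cep_thickness) <= 0))
    stop("all lengths must be positive")
  if (2 * cep_thickness >= disc_height)
    stop("2 * cep_thickness must be < disc_height")
  if (np_area_fraction <= 0 || np_area_fraction >= 1)
    stop("np_area_fraction must lie in (0, 1)")
  if (bean_concavity < 0 || bean_concavity > 0.5)
    stop("bean_concavity must lie in [0, 0.5]")
  structure(list(ap_depth = ap_depth, lat_width = lat_width,
                 disc_height = disc_height, cep_thickness = cep_thickness,
                 np_area_fraction = np_area_fraction,
                 bean_concavity = bean_concavity),
            class = "disc_geometry")
}

# in-plane map of the half-disc: (s, tv) in [0,1] x [-1,1] -> (x, y) in mm;
# square-to-ellipse map plus a posterior indent near the mid-sagittal plane
disc_plane_map <- function(s, tv, geom) {
  a <- geom$lat_width / 2
  b <- geom$ap_depth / 2
  x <- a * s * sqrt(1 - tv^2 / 2)
  y <- b * tv * sqrt(1 - s^2 / 2)
  y <- y + geom$bean_concavity * b * exp(-(s / 0.45)^2) * pmax(0, -tv)^1.5
  cbind(x, y)
}

# structured hex mesh from a 2-D footprint grid and a z-level vector
build_structured_hex <- function(xy_grid, nx1, ny1, z_levels) {
  nz1 <- length(z_levels)
  n_plane <- nx1 * ny1
  nodes <- cbind(
    rep(xy_grid[, 1], nz1),
    rep(xy_grid[, 2], nz1),
    rep(z_levels, each = n_plane))
  nid <- function(ix, iy, iz) ix + (iy - 1L) * nx1 + (iz - 1L) * n_plane
  ex <- rep(seq_len(nx1 - 1L), times = (ny1 - 1L) * (nz1 - 1L))
  ey <- rep(rep(seq_len(ny1 - 1L), each = nx1 - 1L), times = nz1 - 1L)
  ez <- rep(seq_len(nz1 - 1L), each = (nx1 - 1L) * (ny1 - 1L))
  elems <- cbind(
    nid(ex, ey, ez), nid(ex + 1L, ey, ez),
    nid(ex + 1L, ey + 1L, ez), nid(ex, ey + 1L, ez),
    nid(ex, ey, ez + 1L), nid(ex + 1L, ey, ez + 1L),
    nid(ex + 1L, ey + 1L, ez + 1L), nid(ex, ey + 1L, ez + 1L))
  list(nodes = nodes, elems = elems, ex = ex, ey = ey, ez = ez)
}

#' Build the three-region half-disc hexahedral mesh
#'
#' Meshes one half of the disc (mid-sagittal symmetry plane at x = 0) with
#' 8-node trilinear hexahedra. The top and bottom element layers span the
#' endplate thickness and are labeled CEP; in the core, elements whose
#' centroid falls inside a posteriorly biased ellipse sized to hold
#' `np_area_fraction` of the cross-section are labeled NP, the rest AF.
#'
#' Boundary node sets: `symmetry` (x = 0; u_x = 0, impermeable), `top` /
#' `bottom` (axial displacement BCs), `lateral` (free rim) and `drained`
#' (zero pore pressure: every exposed exterior surface including the
#' endplate faces, but not the symmetry plane).
#'
#' @param geom A [disc_geometry()].
#' @param resolution Elements across each in-plane axis (>= 4).
#' @return An object of class `fe_mesh` with `nodes` (m), `elems`,
#'   `region` (per element), and `sets`.
#' @export
build_disc_mesh <- function(geom = disc_geometry(), resolution = 8L) {
  stopifnot(inherits(geom, "disc_geometry"))
  if (resolution < 4) stop("resolution must be >= 4")
  nx <- as.integer(resolution); ny <- as.integer(resolution)
  s <- seq(0, 1, length.out = nx + 1L)
  tv <- seq(-1, 1, length.out = ny + 1L)
  gsv <- rep(s, times = ny + 1L)
  gtv <- rep(tv, each = nx + 1L)
  xy <- disc_plane_map(gsv, gtv, geom)

  cep <- geom$cep_thickness
  core <- geom$disc_height - 2 * cep
  n_core <- max(2L, as.integer(resolution) - 2L)
  z_levels <- c(0, cep, cep + core * seq_len(n_core) / n_core,
                geom$disc_height)
  z_levels <- unique(z_levels)

  m <- build_structured_hex(xy, nx + 1L, ny + 1L, z_levels)
  nz1 <- length(z_levels)

  # region labels
  cent <- element_centroids(m$nodes, m$elems)
  region <- rep("AF", nrow(m$elems))
  is_cep <- m$ez == 1L | m$ez == nz1 - 1L
  region[is_cep] <- "CEP"
  # NP ellipse sized by bisection on the in-plane area fraction
  a <- geom$lat_width / 2; b <- geom$ap_depth / 2
  y0 <- -0.08 * geom$ap_depth
  core_lay <- which(m$ez == 2L)  # one representative core layer
  areas <- element_plane_areas(m$nodes, m$elems[core_lay, , drop = FALSE])
  cx <- cent[core_lay, 1]; cy <- cent[core_lay, 2]
  frac_in <- function(sf)
    sum(areas[(cx / (sf * a))^2 + ((cy - y0) / (sf * b))^2 <= 1]) / sum(areas)
  lo <- 0.05; hi <- 0.98
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac_in(mid) < geom$np_area_fraction) lo <- mid else hi <- mid
  }
  sf <- (lo + hi) / 2
  in_np <- (cent[, 1] / (sf * a))^2 + ((cent[, 2] - y0) / (sf * b))^2 <= 1
  region[!is_cep & in_np] <- "NP"

  nodes_m <- m$nodes * 1e-3  # mm -> m
  nx1 <- nx + 1L; ny1 <- ny + 1L
  ix <- rep(seq_len(nx1), times = ny1 * nz1)
  iy <- rep(rep(seq_len(ny1), each = nx1), times = nz1)
  iz <- rep(seq_len(nz1), each = nx1 * ny1)
  sets <- list(
    symmetry = which(ix == 1L),
    top = which(iz == nz1),
    bottom = which(iz == 1L),
    lateral = which(ix == nx1 | iy == 1L | iy == ny1))
  sets$drained <- sort(unique(c(sets$lateral, sets$top, sets$bottom)))

  structure(list(nodes = nodes_m, elems = m$elems, region = region,
                 sets = sets, kind = "half_disc",
                 height = geom$disc_height * 1e-3, geom = geom),
            class = "fe_mesh")
}

#' Build a homogeneous cylinder mesh for unconfined-compression validation
#'
#' Full cylinder between frictionless impermeable platens with a
#' free-draining lateral surface, matching the boundary conditions of the
#' classical unconfined-compression series solution.
#'
#' @param radius Cylinder radius, m.
#' @param height Cylinder height, m.
#' @param n_r Elements across the diameter (even, >= 4).
#' @param n_z Element layers through the height.
#' @return An `fe_mesh` with a single region `"ALL"` and `drained` set to
#'   the lateral surface only.
#' @export
build_cylinder_mesh <- function(radius, height, n_r = 8L, n_z = 4L) {
  if (n_r < 4 || n_r %% 2 != 0) stop("n_r must be even and >= 4")
  s <- seq(-1, 1, length.out = n_r + 1L)
  gsv <- rep(s, times = n_r + 1L)
  gtv <- rep(s, each = n_r + 1L)
  xy <- cbind(radius * gsv * sqrt(1 - gtv^2 / 2),
              radius * gtv * sqrt(1 - gsv^2 / 2))
  z_levels <- height * seq(0, n_z) / n_z
  m <- build_structured_hex(xy, n_r + 1L, n_r + 1L, z_levels)
  nx1 <- n_r + 1L; nz1 <- n_z + 1L
  ix <- rep(seq_len(nx1), times = nx1 * nz1)
  iy <- rep(rep(seq_len(nx1), each = nx1), times = nz1)
  iz <- rep(seq_len(nz1), each = nx1 * nx1)
  sets <- list(
    symmetry = integer(0),
    top = which(iz == nz1),
    bottom = which(iz == 1L),
    lateral = which(ix == 1L | ix == nx1 | iy == 1L | iy == nx1))
  sets$drained <- sets$lateral
  structure(list(nodes = m$nodes, elems = m$elems,
                 region = rep("ALL", nrow(m$elems)), sets = sets,
                 kind = "cylinder", height = height),
            class = "fe_mesh")
}

element_centroids <- function(nodes, elems) {
  cent <- matrix(0, nrow(elems), 3)
  for (a in 1:8) cent <- cent + nodes[elems[, a], , drop = FALSE]
  cent / 8
}

# in-plane (x, y) area of the bottom face of each element (shoelace)
element_plane_areas <- function(nodes, elems) {
  x <- matrix(nodes[elems[, 1:4], 1], ncol = 4)
  y <- matrix(nodes[elems[, 1:4], 2], ncol = 4)
  0.5 * abs(
    x[, 1] * y[, 2] - x[, 2] * y[, 1] + x[, 2] * y[, 3] - x[, 3] * y[, 2] +
    x[, 3] * y[, 4] - x[, 4] * y[, 3] + x[, 4] * y[, 1] - x[, 1] * y[, 4])
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh %s> %d nodes, %d hex elements\n", x$kind,
              nrow(x$nodes), nrow(x$elems)))
  print(table(x$region))
  invisible(x)
}

#' Element Jacobian determinants at Gauss points
#'
#' Used to verify mesh validity (all determinants must be positive) and by
#' the assembly routines.
#'
#' @param mesh An `fe_mesh`.
#' @return Matrix (n_elements x 8) of Jacobian determinants.
#' @export
element_jacobians <- function(mesh) {
  pre <- fem_precompute(mesh)
  pre$detJ
}

#' Total mesh volume and per-region volumes
#'
#' @param mesh An `fe_mesh`.
#' @return Named list with `total` (m^3) and `by_region`.
#' @export
mesh_volumes <- function(mesh) {
  pre <- fem_precompute(mesh)
  ev <- rowSums(pre$wdet)
  list(total = sum(ev),
       by_region = tapply(ev, mesh$region, sum))
}
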