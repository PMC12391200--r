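# Regional mean materials (confined-compression means; thicknesses from the
# preparation protocol) used across the suite.
region_means <- list(
  NP = list(mat = biphasic_material(0.44e6, 2.96e-16, phi_w0 = 0.873),
            h = 1.17e-3, swp = 97.86e3),
  AF = list(mat = biphasic_material(0.57e6, 2.75e-16, phi_w0 = 0.817),
            h = 1.17e-3, swp = 161.37e3),
  CEP = list(mat = biphasic_material(1.19e6, 1.93e-16, phi_w0 = 0.693),
             h = 0.92e-3, swp = 193.57e3))

# Noise-free synthetic creep trace from known parameters.
make_trace <- function(H_A = 0.5e6, k = 3e-16, h = 1e-3, sigma0 = 30e3,
                       t_ramp = 300, t_end = 7200, by = 10,
                       quantize = FALSE) {
  geom <- specimen_geometry(h)
  m <- biphasic_material(H_A, k, phi_w0 = 0.8)
  tt <- seq(0, t_end, by = by)
  d <- creep_strain_ramp(m, h, sigma0, t_ramp, tt) * h
  if (quantize) d <- round(d * 1e6) / 1e6
  creep_trace(tt, d, sigma0 * geom$area, geom, "NP",
              equilibrium_load = sigma0 * geom$area / 0.2)
}

# Shared expensive FE fixtures, computed at most once per test run.
fe_cache <- new.env(parent = emptyenv())
fe_fixture <- function(name, builder) {
  if (is.null(fe_cache[[name]])) fe_cache[[name]] <- builder()
  fe_cache[[name]]
}
disc8_result <- function()
  fe_fixture("disc8", function()
    solve_biphasic_fem(build_disc_mesh(resolution = 8),
                       default_disc_materials()))
disc8_swelling_result <- function()
  fe_fixture("disc8_sw", function()
    solve_biphasic_fem(build_disc_mesh(resolution = 8),
                       default_disc_materials(), swelling = TRUE))
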