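test_that("von Mises matches the eigenvalue-based oracle", {
  expect_equal(von_mises(c(5, 5, 5, 0, 0, 0)), 0)
  expect_equal(von_mises(c(-7, 0, 0, 0, 0, 0)), 7)
  set.seed(31)
  for (i in 1:20) {
    S <- matrix(rnorm(9), 3); S <- S + t(S)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    oracle <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                            (ev[3] - ev[1])^2))
    expect_equal(
      von_mises(c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[2, 3], S[3, 1])),
      oracle, tolerance = 1e-12)
  }
})

test_that("fluid flux reproduces exact and manufactured pressure fields", {
  mesh <- build_cylinder_mesh(3e-3, 2e-3, n_r = 8, n_z = 4)
  k <- 2.75e-16
  # uniform pressure: zero flux
  fx <- fluid_flux(mesh, rep(1e4, nrow(mesh$nodes)), k)
  expect_lt(max(abs(fx)), 1e-20)
  # linear drop across the height: w_z = k dp/dz exactly (trilinear basis
  # reproduces linear fields)
  dp_dz <- -5e6  # Pa / m
  p_lin <- 1e4 + dp_dz * mesh$nodes[, 3]
  fx <- fluid_flux(mesh, p_lin, k)
  expect_equal(fx[, 3], rep(-k * dp_dz, nrow(mesh$elems)), tolerance = 1e-9)
  expect_lt(max(abs(fx[, 1:2])), 1e-12 * abs(k * dp_dz))
  # manufactured quadratic p = x^2: element-mean flux ~ -2 k x_centroid
  p_quad <- mesh$nodes[, 1]^2 * 1e9
  fx <- fluid_flux(mesh, p_quad, k)
  cent <- discmech:::element_centroids(mesh$nodes, mesh$elems)
  expect_lt(stats::median(abs(fx[, 1] + 2e9 * k * cent[, 1]) /
                            (2e9 * k * 3e-3)), 0.05)
})

test_that("zero applied strain with swelling off gives the zero solution", {
  mesh <- build_cylinder_mesh(2e-3, 1.5e-3, n_r = 4, n_z = 2)
  m <- biphasic_material(0.5e6, 3e-16, phi_w0 = 0.8)
  res <- solve_biphasic_fem(mesh, list(ALL = m),
                            fem_protocol(strain = 1e-300,
                                         ramp_duration = 100,
                                         hold_end = 200))
  expect_lt(max(abs(res$reaction)), 1e-12)
  expect_lt(max(abs(res$P[[length(res$P)]])), 1e-12)
  expect_lt(max(abs(res$stress[[length(res$stress)]])), 1e-12)
})

test_that("homogeneous cylinder matches the unconfined series to < 3%", {
  m <- biphasic_material(0.57e6, 2.75e-16, nu = 0.2, phi_w0 = 0.817)
  a <- 3e-3
  mesh <- build_cylinder_mesh(a, 2e-3, n_r = 8, n_z = 3)
  prot <- fem_protocol(strain = 0.10, ramp_duration = 1e4, hold_end = 2e5)
  res <- solve_biphasic_fem(mesh, list(ALL = m), prot)
  F_an <- unconfined_reaction_ramp(m, a, 0.10, 1e4, res$step_times) *
    (pi * a^2)
  rel <- abs(res$reaction - F_an) / max(F_an)
  expect_lt(max(rel), 0.03)
  # drained-face pressures stay at solver zero
  for (i in seq_along(res$times)) {
    p <- res$P[[i]]
    expect_lt(max(abs(p[mesh$sets$drained])),
              1e-9 * max(abs(p), 1))
  }
})

test_that("volume change equals the drained Poisson contraction", {
  # at drained equilibrium the cylinder is in uniaxial stress:
  # tr(eps) = -eps0 (1 - 2 nu); integral test of the coupling terms
  m <- biphasic_material(0.5e6, 3e-16, nu = 0.2, phi_w0 = 0.8)
  mesh <- build_cylinder_mesh(2e-3, 1.5e-3, n_r = 6, n_z = 2)
  res <- solve_biphasic_fem(mesh, list(ALL = m),
                            fem_protocol(strain = 0.1, ramp_duration = 1e3,
                                         hold_end = 50 * 4e-6 / (0.5e6 * 3e-16)))
  i <- length(res$times)
  S <- res$stress[[i]]
  tr_sig <- S[, 1] + S[, 2] + S[, 3]
  E <- young_from_aggregate(m$H_A, m$nu)
  # uniaxial drained stress state: sigma_zz = -E eps0, others ~ 0
  expect_equal(stats::median(S[, 3]), -E * 0.1, tolerance = 0.02)
  expect_lt(stats::median(abs(S[, 1])) / (E * 0.1), 0.03)
})

test_that("three-region disc reproduces the regional ordering", {
  res <- disc8_result()
  pk <- peak_table(res, times = 1e4)
  expect_gt(pk$stress_MPa[pk$region == "CEP"],
            pk$stress_MPa[pk$region == "NP"])
  # pressure decays >= 4 orders of magnitude over the hold
  pk_end <- peak_table(res, times = 4e5)
  expect_lt(max(pk_end$pressure_kPa), 1e-4 * max(pk$pressure_kPa))
  # pressure oscillation stayed bounded
  expect_lte(res$oscillation, 1)
})

test_that("swelling raises region peak stresses and pre-swells the disc", {
  res_sw <- disc8_swelling_result()
  res <- disc8_result()
  pk <- peak_table(res, times = 1e4)
  pk_sw <- peak_table(res_sw, times = 1e4)
  for (reg in c("NP", "AF", "CEP"))
    expect_gt(pk_sw$stress_MPa[pk_sw$region == reg],
              pk$stress_MPa[pk$region == reg])
  # free swelling lifts the top surface
  expect_gt(max(res_sw$swollen_state[, 3]), 0)
  # swelling model also ends near-drained
  pk_sw_end <- peak_table(res_sw, times = 4e5)
  expect_lt(max(pk_sw_end$pressure_kPa), 1e-4 * max(pk_sw$pressure_kPa))
})

test_that("identical materials leave no spurious NP/AF contrast", {
  mats <- default_disc_materials()
  same <- list(NP = mats$AF, AF = mats$AF, CEP = mats$AF)
  res <- solve_biphasic_fem(build_disc_mesh(resolution = 8), same)
  pk <- peak_table(res, times = 1e4)
  s_np <- pk$stress_MPa[pk$region == "NP"]
  s_af <- pk$stress_MPa[pk$region == "AF"]
  expect_lt(abs(s_np - s_af) / s_af, 0.10)
})

test_that("region peak stresses are stable under mesh refinement", {
  r8 <- disc8_result()
  r12 <- solve_biphasic_fem(build_disc_mesh(resolution = 12),
                            default_disc_materials())
  p8 <- peak_table(r8, 1e4)
  p12 <- peak_table(r12, 1e4)
  for (reg in c("NP", "AF", "CEP")) {
    a <- p8$stress_MPa[p8$region == reg]
    b <- p12$stress_MPa[p12$region == reg]
    expect_lt(abs(a - b) / b, 0.05)
  }
})
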