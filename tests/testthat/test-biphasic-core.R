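test_that("aggregate <-> Young conversions match the material table", {
  # printed table: H_A 1.19 / 0.57 / 0.44 MPa with nu = 0.2 alongside
  # E 1.07 / 0.52 / 0.39 MPa
  expect_equal(round(young_from_aggregate(1.19e6, 0.2) / 1e6, 2), 1.07)
  expect_lt(abs(young_from_aggregate(0.44e6, 0.2) / 1e6 - 0.39), 0.01)
  expect_lt(abs(young_from_aggregate(0.57e6, 0.2) / 1e6 - 0.52), 0.01)
  # nu = 0 identity, both directions
  expect_equal(young_from_aggregate(123.4, 0), 123.4)
  expect_equal(aggregate_from_young(123.4, 0), 123.4)
  # algebraic inverse: E = 1.07 MPa back to H_A
  expect_equal(aggregate_from_young(1.07e6, 0.2), 1.07e6 * 0.8 / (1.2 * 0.6))
  expect_error(young_from_aggregate(1e6, 0.5), "nu")
  expect_error(young_from_aggregate(1e6, -0.1), "nu")
  expect_error(aggregate_from_young(-1, 0.2), "positive")
})

test_that("conversion round-trip and monotonicity hold over random draws", {
  set.seed(11)
  for (i in 1:50) {
    H <- runif(1, 1e4, 5e6)
    nu <- runif(1, 0, 0.49)
    E <- young_from_aggregate(H, nu)
    expect_lte(E, H)
    expect_gt(E, 0)
    expect_equal(aggregate_from_young(E, nu), H, tolerance = 1e-12)
  }
  nus <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(young_from_aggregate(1e6, nus)) < 0))
  Hs <- seq(1e5, 5e6, length.out = 60)
  expect_true(all(diff(young_from_aggregate(Hs, 0.2)) > 0))
})

test_that("permeability report-unit conversion matches the table pairing", {
  # SI 1e-16 m^4/N/s values read identically in 1e-4 mm^4/N/s
  expect_equal(permeability_to_report_units(2.75e-16), 2.75)
  expect_equal(permeability_to_report_units(1.93e-16), 1.93)
  expect_equal(permeability_to_report_units(0), 0)
  expect_error(permeability_to_report_units(-1e-16), ">= 0")
})

test_that("gel time scales correctly and orders the regions", {
  af <- region_means$AF
  expect_equal(gel_time(af$mat, af$h), 1.17e-3^2 / (0.57e6 * 2.75e-16),
               tolerance = 1e-12)
  expect_equal(gel_time(af$mat, af$h) / 1e3, 8.733, tolerance = 1e-3)
  expect_equal(gel_time(af$mat, 2 * af$h), 4 * gel_time(af$mat, af$h))
  np <- region_means$NP; cep <- region_means$CEP
  expect_gt(gel_time(np$mat, np$h), gel_time(cep$mat, cep$h))
})

test_that("step creep strain has the exact limits and stays monotone", {
  np <- region_means$NP
  s0 <- 0.2 * np$swp
  expect_identical(creep_strain_step(np$mat, np$h, s0, 0), 0)
  tau <- gel_time(np$mat, np$h)
  expect_equal(creep_strain_step(np$mat, np$h, s0, 20 * tau),
               s0 / np$mat$H_A, tolerance = 1e-9)
  set.seed(21)
  for (i in 1:10) {
    m <- biphasic_material(runif(1, 0.1e6, 2e6), runif(1, 0.5e-16, 6e-16),
                           phi_w0 = 0.8)
    h <- runif(1, 0.5e-3, 2e-3)
    tg <- seq(0, 3 * gel_time(m, h), length.out = 80)
    eps <- creep_strain_step(m, h, 25e3, tg)
    expect_true(all(diff(eps) >= -1e-14))
    expect_true(all(eps <= 25e3 / m$H_A + 1e-12))
  }
})

test_that("equilibrium strain is independent of permeability", {
  m1 <- biphasic_material(0.5e6, 1e-16, phi_w0 = 0.8)
  m2 <- biphasic_material(0.5e6, 5e-16, phi_w0 = 0.8)
  h <- 1e-3
  t_eq <- 50 * max(gel_time(m1, h), gel_time(m2, h))
  e1 <- creep_strain_step(m1, h, 30e3, t_eq)
  e2 <- creep_strain_step(m2, h, 30e3, t_eq)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("ramped creep reduces to the step solution and lags it", {
  m <- biphasic_material(0.5e6, 3e-16, phi_w0 = 0.8)
  h <- 1e-3
  tau <- gel_time(m, h)
  tg <- seq(60, 2 * tau, length.out = 40)
  step <- creep_strain_step(m, h, 30e3, tg)
  tiny <- creep_strain_ramp(m, h, 30e3, 1e-6, tg)
  expect_equal(tiny, step, tolerance = 1e-6)
  ramp <- creep_strain_ramp(m, h, 30e3, 300, tg)
  expect_true(all(ramp <= step + 1e-12))
  expect_equal(creep_strain_ramp(m, h, 30e3, 300, 30 * tau),
               30e3 / m$H_A, tolerance = 1e-8)
})

test_that("relaxation stress peaks at ramp end and decays to H_A * eps0", {
  cep <- region_means$CEP
  tau <- gel_time(cep$mat, cep$h)
  tg <- c(seq(10, 300, by = 10), seq(310, 3600, by = 25), 30 * tau)
  sig <- relaxation_stress(cep$mat, cep$h, 0.10, 300, tg)
  eq <- cep$mat$H_A * 0.10
  expect_equal(sig[length(sig)], eq, tolerance = 1e-8)
  i_peak <- which.max(sig)
  expect_equal(tg[i_peak], 300)
  post <- sig[tg >= 300]
  expect_true(all(diff(post) <= 1e-9 * eq))
  expect_true(all(post >= eq - 1e-9 * eq))
})

test_that("series solutions agree with the finite-difference oracle", {
  # mean-parameter cases from each region, ramped and stepped
  np <- region_means$NP
  g <- oracle_grid(np$mat, np$h, 7200)
  sol <- solve_consolidation(np$mat, np$h,
                             load_history("stress_control", 0, 0.2 * np$swp),
                             g)
  eps_an <- creep_strain_step(np$mat, np$h, 0.2 * np$swp, sol$t)
  expect_lt(max(abs(sol$surface_displacement / np$h - eps_an)) / max(eps_an),
            1e-3)

  af <- region_means$AF
  g2 <- oracle_grid(af$mat, af$h, 7200, ramp_duration = 300)
  sol2 <- solve_consolidation(af$mat, af$h,
    load_history("stress_control", c(0, 300), c(0, 0.2 * af$swp)), g2)
  eps_an2 <- creep_strain_ramp(af$mat, af$h, 0.2 * af$swp, 300, sol2$t)
  expect_lt(max(abs(sol2$surface_displacement / af$h - eps_an2)) /
              max(eps_an2), 1e-3)

  cep <- region_means$CEP
  g3 <- oracle_grid(cep$mat, cep$h, 3600, ramp_duration = 300)
  sol3 <- solve_consolidation(cep$mat, cep$h,
    load_history("displacement_control", c(0, 300), c(0, 0.10)), g3)
  sig_an <- relaxation_stress(cep$mat, cep$h, 0.10, 300, sol3$t)
  i <- sol3$t > 0
  expect_lt(max(abs(sol3$reaction_stress[i] - sig_an[i])) / max(sig_an),
            1e-3)
})

test_that("series kernels error informatively when the term cap is hit", {
  ctl <- series_control(tol = 1e-12, n_max = 3L)
  m <- region_means$NP$mat
  expect_error(
    creep_strain_step(m, 1.17e-3, 1e4, 0.06 * gel_time(m, 1.17e-3),
                      ctl = ctl),
    "not converged")
})

test_that("type constructors validate their invariants", {
  expect_error(biphasic_material(-1, 1e-16), "positive")
  expect_error(biphasic_material(1e6, 0), "positive")
  expect_error(biphasic_material(1e6, 1e-16, nu = 0.6), "0.5")
  expect_error(biphasic_material(1e6, 1e-16, phi_w0 = 1.2), "porosity")
  expect_error(specimen_geometry(0), "> 0")
  g <- specimen_geometry(1e-3)
  expect_equal(g$area, pi * (5e-3)^2 / 4)
  expect_error(load_protocol(offset_strain = 1.2), "offset_strain")
  expect_error(load_protocol(creep_load_fraction = 0), "creep_load_fraction")
  expect_error(series_control(tol = -1), "tol")
})

test_that("image-form kernels agree with long spectral sums", {
  # independent oracle: plain eigenfunction sums with 5000 terms, evaluated
  # where they still converge but the package already uses the image (erfc)
  # branch (x < 0.05)
  ctl <- series_control()
  n <- 0:4999
  M2 <- ((n + 0.5) * pi)^2
  lam <- (n[-1] * pi)^2  # n = 1..4999 for the relaxation family
  for (x in c(0.005, 0.02, 0.049)) {
    u_spec <- 1 - sum(2 * exp(-M2 * x) / M2)
    expect_equal(discmech:::kernel_creep_step(x, ctl), u_spec,
                 tolerance = 1e-10)
    phi_spec <- x - 1 / 3 + sum(2 / M2^2 * exp(-M2 * x))
    expect_equal(discmech:::kernel_creep_int(x, ctl), phi_spec,
                 tolerance = 1e-9)
    f_spec <- x + 1 / 3 - sum(2 / lam * exp(-lam * x))
    expect_equal(discmech:::kernel_relax_int(x, ctl), f_spec,
                 tolerance = 1e-9)
  }
})
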