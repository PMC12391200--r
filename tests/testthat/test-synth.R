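test_that("specimen sampling is deterministic in the seed", {
  pr <- regional_priors()
  a <- sample_specimen("AF", pr, seed = 123)
  b <- sample_specimen("AF", pr, seed = 123)
  expect_identical(a$true_material$H_A, b$true_material$H_A)
  expect_identical(a$true_porosity, b$true_porosity)
  c <- sample_specimen("AF", pr, seed = 124)
  expect_false(identical(a$true_material$H_A, c$true_material$H_A))
})

test_that("sampled means match an independent reimplementation", {
  # oracle: straight-line reimplementation of the stated sampling rules
  # (shared latent factor, truncation at 10% of the mean, strain guard),
  # kept free of any package code
  pr <- regional_priors()
  row <- pr$regions[pr$regions$region == "NP", ]
  ell <- sqrt(pr$latent_coupling)
  set.seed(5150)
  n_mc <- 20000
  draw1 <- function(mean, sd, z, load, lo) {
    repeat {
      x <- mean + sd * (load * z + sqrt(1 - load^2) * rnorm(1))
      if (x >= lo) return(x)
    }
  }
  oracle <- replicate(n_mc, {
    repeat {
      z <- rnorm(1)
      H <- draw1(row$H_A_MPa, row$H_A_sd, z, -ell, 0.1 * row$H_A_MPa)
      s <- draw1(row$swp_kPa, row$swp_sd, z, -ell, 0.1 * row$swp_kPa)
      if (0.2 * s * 1e3 / (H * 1e6) <= 0.15) return(H)
    }
  })
  draws <- vapply(1:1000, function(i)
    sample_specimen("NP", pr, seed = 31000 + i)$true_material$H_A / 1e6,
    numeric(1))
  se <- sqrt(stats::sd(draws)^2 / 1000 + stats::sd(oracle)^2 / n_mc)
  expect_lt(abs(mean(draws) - mean(oracle)), 3 * se)
})

test_that("pooled porosity-stiffness coupling lands in the target band", {
  pr <- regional_priors()
  regs <- rep(c("AF", "NP", "CEP"), length.out = 300)
  H <- phi <- numeric(300)
  for (i in seq_along(regs)) {
    s <- sample_specimen(regs[i], pr, seed = 2000 + i)
    H[i] <- s$true_material$H_A
    phi[i] <- s$true_porosity
  }
  r <- pearson_corr(phi, H)$r
  expect_gte(r, -0.65)
  expect_lte(r, -0.40)
})

test_that("the generator never emits a linear-theory-violating specimen", {
  pr <- regional_priors()
  for (i in 1:200) {
    reg <- c("AF", "NP", "CEP")[1 + i %% 3]
    s <- sample_specimen(reg, pr, seed = 52000 + i)
    eps_eq <- 0.2 * s$true_swelling_pressure / s$true_material$H_A
    expect_lte(eps_eq, 0.15)
    expect_gte(attr(s, "n_resampled"), 0)
  }
})

test_that("simulated DMA traces honor quantization and construction", {
  pr <- regional_priors()
  s <- sample_specimen("CEP", pr, seed = 61)
  dma <- simulate_dma(s, quantize = TRUE)
  um <- dma$creep$displacement * 1e6
  expect_equal(um, round(um))
  mN <- dma$relaxation$force * 1e3
  expect_equal(mN, round(mN))
  # relaxation equilibrium reproduces the true swelling pressure within one
  # force quantum over the area
  area <- s$geometry$area
  expect_lt(abs(dma$relaxation$equilibrium_load / area -
                  s$true_swelling_pressure), 1e-3 / area + 1e-9)
})

test_that("noise-free DMA round-trips through the fitter within 1%", {
  pr <- regional_priors()
  for (reg in c("NP", "AF", "CEP")) {
    s <- sample_specimen(reg, pr, seed = 71 + match(reg, c("NP", "AF", "CEP")))
    dma <- simulate_dma(s, quantize = FALSE)
    fit <- suppressWarnings(fit_biphasic_creep(dma$creep))
    expect_lt(abs(fit$H_A_hat - s$true_material$H_A) / s$true_material$H_A,
              0.01)
    expect_lt(abs(fit$k_hat - s$true_material$k) / s$true_material$k, 0.01)
  }
})

test_that("buoyancy weights invert exactly and degrade gracefully", {
  pr <- regional_priors()
  s <- sample_specimen("AF", pr, seed = 81)
  w <- simulate_weights(s)
  expect_equal(porosity(w), s$true_porosity, tolerance = 1e-12)
  errs <- vapply(1:50, function(i) {
    wn <- simulate_weights(s, seed = 8100 + i, balance_noise_mg = 0.1)
    porosity(wn) - s$true_porosity
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 0.02)
})

test_that("cohort generation is reproducible and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  t1 <- generate_cohort(d1, master_seed = 17)
  t2 <- generate_cohort(d2, master_seed = 17)
  expect_equal(nrow(t1), 36)  # default 16 AF + 10 NP + 10 CEP
  expect_identical(readBin(file.path(d1, "ground_truth.csv"), "raw", 1e6),
                   readBin(file.path(d2, "ground_truth.csv"), "raw", 1e6))
  expect_true(file.exists(file.path(d1, "weights.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_length(list.files(d1, pattern = "^AF_..\\.csv$"), 16)
  expect_setequal(unique(t1$region), c("AF", "NP", "CEP"))
  expect_length(unique(t1$donor_id), 3)
})

test_that("region-mean H_A estimates track the generative truth", {
  # 20 seeded replicates of the quantized default cohort; the fitted region
  # mean should fall within 2 cohort SEs of the generator's true regional
  # mean (computed from the same replicate's specimens) in >= 90% of
  # region-replicate pairs
  pr <- regional_priors()
  n_per <- c(AF = 16, NP = 10, CEP = 10)
  ok <- 0L; tot <- 0L
  for (rep_i in 1:20) {
    for (reg in names(n_per)) {
      hats <- truths <- numeric(n_per[[reg]])
      for (j in seq_len(n_per[[reg]])) {
        sd_ <- 90000 + rep_i * 997 + match(reg, names(n_per)) * 131 + j
        s <- sample_specimen(reg, pr, seed = sd_)
        dma <- simulate_dma(s, seed = sd_ + 1, quantize = TRUE)
        fit <- suppressWarnings(fit_biphasic_creep(dma$creep))
        hats[j] <- fit$H_A_hat
        truths[j] <- s$true_material$H_A
      }
      se <- stats::sd(hats) / sqrt(length(hats))
      tot <- tot + 1L
      if (abs(mean(hats) - mean(truths)) <= 2 * se) ok <- ok + 1L
    }
  }
  expect_gte(ok / tot, 0.9)
})
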