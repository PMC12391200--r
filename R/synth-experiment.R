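#' Regional prior distributions for the synthetic cohort generator
#'
#' Default per-region means and spreads for aggregate modulus, permeability,
#' swelling pressure, porosity and specimen thickness, matching the measured
#' cervical-disc cohort: confined-compression means +/- SD for H_A and k,
#' swelling-pressure means with SDs backed out of the reported 95% CIs, mean
#' porosities consistent with the FE solid fractions, and preparation
#' thicknesses of 1.17 +/- 0.35 mm (disc tissue) / 0.92 +/- 0.21 mm (CEP).
#'
#' `latent_coupling` sets the loading of a shared standard-normal
#' "composition" factor that raises porosity while lowering stiffness and
#' swelling pressure (and weakly raising permeability), calibrated once so
#' that the pooled Pearson correlation between porosity and aggregate modulus
#' lands near -0.5.
#'
#' @param latent_coupling Shared-factor coupling in `[0, 1]`.
#' @return An object of class `regional_priors`: a list with a `regions`
#'   data frame and the coupling constant.
#' @export
regional_priors <- function(latent_coupling = 0.25) {
  if (!is.finite(latent_coupling) || latent_coupling < 0 ||
      latent_coupling > 1)
    stop("latent_coupling must lie in [0, 1]")
  regions <- data.frame(
    region = c("AF", "NP", "CEP"),
    H_A_MPa = c(0.57, 0.44, 1.19),
    H_A_sd = c(0.48, 0.44, 0.98),
    k_e16 = c(2.75, 2.96, 1.93),
    k_sd = c(2.29, 2.51, 1.74),
    swp_kPa = c(161.37, 97.86, 193.57),
    swp_sd = c(89.1, 81.3, 82.8),
    porosity = c(0.817, 0.873, 0.693),
    porosity_sd = c(0.05, 0.05, 0.05),
    thickness_mm = c(1.17, 1.17, 0.92),
    thickness_sd = c(0.35, 0.35, 0.21),
    fcd_mM = c(135.5, 182.2, 286.7),
    stringsAsFactors = FALSE)
  structure(list(regions = regions, latent_coupling = latent_coupling),
            class = "regional_priors")
}

# truncated-normal draw: lower truncation at `lo`, optional upper `hi`;
# the correlated part (load * z) is kept, only the idiosyncratic part is
# redrawn, preserving the latent-factor structure under truncation
draw_trunc <- function(mean, sd, z, load, lo, hi = Inf) {
  for (i in 1:200) {
    x <- mean + sd * (load * z + sqrt(1 - load^2) * stats::rnorm(1))
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)  # pathological prior; fall back to the mean
}

#' Draw one synthetic specimen
#'
#' True material parameters are truncated-normal draws (lower truncation at
#' 10% of the regional mean) around the regional priors; porosity, stiffness,
#' swelling pressure and permeability share a latent composition factor (see
#' [regional_priors()]). Draws whose protocol-implied creep equilibrium
#' strain `0.2 * swp / H_A` would exceed 15% violate the small-strain premise
#' and are resampled, with the resample count recorded in attribute
#' `"n_resampled"`.
#'
#' @param region `"NP"`, `"AF"` or `"CEP"`.
#' @param priors A [regional_priors()].
#' @param seed Integer seed; the same seed reproduces the same specimen.
#' @param specimen_id,donor_id,disc_level Labels.
#' @param mean_shift Optional named numeric vector of additive shifts applied
#'   to the regional means (used for donor effects), in prior units.
#' @return An object of class `synthetic_specimen`.
#' @export
sample_specimen <- function(region, priors = regional_priors(), seed = 1L,
                            specimen_id = NULL, donor_id = "D1",
                            disc_level = "C4-C5", mean_shift = NULL) {
  stopifnot(inherits(priors, "regional_priors"))
  row <- priors$regions[priors$regions$region == region, ]
  if (nrow(row) != 1L) stop("unknown region: ", region)
  shift <- function(nm) if (!is.null(mean_shift) && nm %in% names(mean_shift))
    mean_shift[[nm]] else 0
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))

  ell <- sqrt(priors$latent_coupling)
  n_resampled <- 0L
  repeat {
    z <- stats::rnorm(1)  # shared composition factor
    H_A <- draw_trunc(row$H_A_MPa + shift("H_A_MPa"), row$H_A_sd, z, -ell,
                      lo = 0.1 * row$H_A_MPa)
    k <- draw_trunc(row$k_e16 + shift("k_e16"), row$k_sd, z, 0.5 * ell,
                    lo = 0.1 * row$k_e16)
    swp <- draw_trunc(row$swp_kPa + shift("swp_kPa"), row$swp_sd, z, -ell,
                      lo = 0.1 * row$swp_kPa)
    phi <- draw_trunc(row$porosity + shift("porosity"), row$porosity_sd, z,
                      ell, lo = 0.40, hi = 0.98)
    th <- draw_trunc(row$thickness_mm + shift("thickness_mm"),
                     row$thickness_sd, 0, 0,
                     lo = 0.1 * row$thickness_mm)
    if (0.2 * swp * 1e3 / (H_A * 1e6) <= 0.15) break
    n_resampled <- n_resampled + 1L
    if (n_resampled > 500L) stop("specimen resampling did not terminate")
  }

  if (is.null(specimen_id))
    specimen_id <- sprintf("%s_%05d", region, as.integer(seed) %% 100000L)
  out <- structure(list(
    specimen_id = specimen_id, region = region, donor_id = donor_id,
    disc_level = disc_level,
    geometry = specimen_geometry(thickness = th * 1e-3),
    true_material = biphasic_material(H_A * 1e6, k * 1e-16,
                                      phi_w0 = phi, c_F0 = row$fcd_mM),
    true_swelling_pressure = swp * 1e3,
    true_porosity = phi),
    class = "synthetic_specimen")
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Simulate a DMA relaxation + creep experiment for one specimen
#'
#' The stress-relaxation phase ramps the offset strain over 60 s and holds
#' it; its force trace is the specimen's swelling-pressure baseline plus the
#' consolidation transient, constructed so the equilibrium load equals
#' `true_swelling_pressure * area`. The creep phase applies 20% of the
#' (measured) equilibrium load over the protocol ramp and records the
#' displacement from the ramped biphasic solution. With `quantize` on,
#' displacement is rounded to 1 um and force to 1 mN, the instrument
#' precisions.
#'
#' @param spec A [sample_specimen()] result.
#' @param protocol A [load_protocol()].
#' @param seed Integer seed (used only when `extra_rms > 0`).
#' @param quantize Apply instrument quantization (default `TRUE`).
#' @param extra_rms Additional white displacement noise, m RMS.
#' @param dt_sample Sampling interval, s.
#' @return List with `relaxation` (a `relaxation_trace`) and `creep`
#'   (a [creep_trace()]).
#' @export
simulate_dma <- function(spec, protocol = load_protocol(), seed = 1L,
                         quantize = TRUE, extra_rms = 0, dt_sample = 10) {
  stopifnot(inherits(spec, "synthetic_specimen"),
            inherits(protocol, "load_protocol"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))

  mat <- spec$true_material
  h <- spec$geometry$thickness
  area <- spec$geometry$area
  eps0 <- protocol$offset_strain
  swp <- spec$true_swelling_pressure
  offset_ramp <- 60  # s; offset compression applied over one minute

  # relaxation phase: baseline (swelling) + consolidation transient,
  # anchored so the final recorded sample equals swp * area exactly (the
  # residual transient at one hour would otherwise bias the equilibrium
  # load for slow specimens)
  t_rel <- seq(0, protocol$relax_duration, by = dt_sample)
  trans <- relaxation_stress(mat, h, eps0, offset_ramp, t_rel)
  sig_rel <- swp - trans[length(trans)] + trans
  f_rel <- pmax(sig_rel, 0) * area
  d_rel <- h * eps0 * pmin(t_rel / offset_ramp, 1)
  if (extra_rms > 0) f_rel <- f_rel + stats::rnorm(length(f_rel),
                                                   sd = extra_rms * mat$H_A)
  if (quantize) {
    f_rel <- round(f_rel * 1e3) / 1e3  # 1 mN
    d_rel <- round(d_rel * 1e6) / 1e6  # 1 um
  }
  eq_load <- f_rel[length(f_rel)]

  # creep phase: 20% of the measured equilibrium load, 5-min ramp
  cl <- creep_load(eq_load, protocol$creep_load_fraction)
  sigma0 <- cl / area
  t_cr <- seq(0, protocol$creep_duration, by = dt_sample)
  d_cr <- creep_strain_ramp(mat, h, sigma0, protocol$ramp_duration, t_cr) * h
  if (extra_rms > 0)
    d_cr <- d_cr + stats::rnorm(length(t_cr), sd = extra_rms)
  if (quantize) d_cr <- round(d_cr * 1e6) / 1e6
  f_cr <- pmin(t_cr / protocol$ramp_duration, 1) * cl
  if (quantize) f_cr <- round(f_cr * 1e3) / 1e3

  relaxation <- structure(list(time = t_rel, force = f_rel,
                               displacement = d_rel,
                               equilibrium_load = eq_load),
                          class = "relaxation_trace")
  creep <- creep_trace(t_cr, d_cr, cl, spec$geometry, spec$region,
                       specimen_id = spec$specimen_id,
                       donor_id = spec$donor_id,
                       disc_level = spec$disc_level,
                       equilibrium_load = eq_load)
  list(relaxation = relaxation, creep = creep)
}

#' Simulate buoyancy weighings for one specimen
#'
#' Wet weight from geometry and a tissue density of 1050 kg m^-3; submerged
#' and dry weights back-solved so the porosity formula returns the
#' specimen's true porosity exactly when `balance_noise_mg = 0`.
#'
#' @param spec A [sample_specimen()] result.
#' @param seed Integer seed (used when noise is on).
#' @param balance_noise_mg Gaussian noise SD added to each weighing, mg.
#' @param tissue_density Tissue density, kg m^-3.
#' @return A [buoyancy_weights()] (weights in mg).
#' @export
simulate_weights <- function(spec, seed = 1L, balance_noise_mg = 0,
                             tissue_density = 1050) {
  stopifnot(inherits(spec, "synthetic_specimen"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  V <- spec$geometry$area * spec$geometry$thickness  # m^3
  mg_per_m3 <- 1e9  # of water (1000 kg/m^3)
  W_wet <- V * tissue_density / 1000 * mg_per_m3
  W_PBS <- W_wet - V * 1.005 * mg_per_m3      # buoyancy of displaced PBS
  W_dry <- W_wet - spec$true_porosity * V * mg_per_m3
  if (balance_noise_mg > 0) {
    W_wet <- W_wet + stats::rnorm(1, sd = balance_noise_mg)
    W_PBS <- W_PBS + stats::rnorm(1, sd = balance_noise_mg)
    W_dry <- W_dry + stats::rnorm(1, sd = balance_noise_mg)
  }
  buoyancy_weights(W_wet, W_PBS, W_dry)
}

#' Generate a complete synthetic cohort on disk
#'
#' Draws specimens per region (default cohort 16 AF / 10 NP / 10 CEP across
#' 3 donors), simulates the DMA protocol and buoyancy weighings, and writes
#' the dataset in the layout consumed by [run_pipeline()]: one creep CSV +
#' JSON sidecar and one relaxation CSV per specimen, a pooled `weights.csv`,
#' a `ground_truth.csv` and a `manifest.json`. Fully reproducible from
#' `master_seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_region Named counts, e.g. `c(AF = 16, NP = 10, CEP = 10)`.
#' @param priors A [regional_priors()].
#' @param master_seed Integer master seed.
#' @param protocol A [load_protocol()].
#' @param quantize,extra_rms,balance_noise_mg Noise settings passed through.
#' @param n_donors Number of donors; donor effects are N(0, (5% regional
#'   SD)^2) shifts of the regional means.
#' @return Invisibly, the ground-truth data frame.
#' @export
generate_cohort <- function(out_dir,
                            n_per_region = c(AF = 16, NP = 10, CEP = 10),
                            priors = regional_priors(), master_seed = 17L,
                            protocol = load_protocol(), quantize = TRUE,
                            extra_rms = 0, balance_noise_mg = 0,
                            n_donors = 3L) {
  stopifnot(all(names(n_per_region) %in% c("AF", "NP", "CEP")),
            all(n_per_region >= 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(master_seed %% 2147483647))

  n_tot <- sum(n_per_region)
  spec_seeds <- sample.int(2147483646L, n_tot + 1000L)
  levels_pool <- c("C2-C3", "C3-C4", "C4-C5", "C5-C6", "C6-C7", "C7-T1")
  donors <- paste0("D", seq_len(n_donors))
  # donor effects: 5% of the regional SD on each property
  donor_shift <- lapply(donors, function(d) {
    s <- stats::rnorm(4, sd = 0.05)
    names(s) <- c("H_A_MPa", "k_e16", "swp_kPa", "porosity")
    s
  })
  names(donor_shift) <- donors

  truth <- NULL
  weights_df <- NULL
  total_resampled <- 0L
  idx <- 0L
  for (region in names(n_per_region)) {
    row <- priors$regions[priors$regions$region == region, ]
    sds <- c(H_A_MPa = row$H_A_sd, k_e16 = row$k_sd,
             swp_kPa = row$swp_sd, porosity = row$porosity_sd)
    for (j in seq_len(n_per_region[[region]])) {
      idx <- idx + 1L
      donor <- donors[1L + (idx - 1L) %% n_donors]
      lvl <- levels_pool[1L + (idx - 1L) %% length(levels_pool)]
      shift <- donor_shift[[donor]] * sds
      sid <- sprintf("%s_%02d", region, j)
      spec <- sample_specimen(region, priors, seed = spec_seeds[idx],
                              specimen_id = sid, donor_id = donor,
                              disc_level = lvl, mean_shift = shift)
      total_resampled <- total_resampled + attr(spec, "n_resampled")
      dma <- simulate_dma(spec, protocol, seed = spec_seeds[idx] + 1L,
                          quantize = quantize, extra_rms = extra_rms)
      w <- simulate_weights(spec, seed = spec_seeds[idx] + 2L,
                            balance_noise_mg = balance_noise_mg)

      cr <- dma$creep
      utils::write.csv(
        data.frame(time_s = cr$time,
                   displacement_um = cr$displacement * 1e6,
                   force_mN = pmin(cr$time / protocol$ramp_duration, 1) *
                     cr$applied_load * 1e3),
        file.path(out_dir, paste0(sid, ".csv")), row.names = FALSE)
      rl <- dma$relaxation
      utils::write.csv(
        data.frame(time_s = rl$time, displacement_um = rl$displacement * 1e6,
                   force_mN = rl$force * 1e3),
        file.path(out_dir, paste0(sid, "_relaxation.csv")), row.names = FALSE)
      jsonlite::write_json(list(
        specimen_id = sid, region = region, donor_id = donor,
        disc_level = lvl,
        thickness_mm = spec$geometry$thickness * 1e3,
        diameter_mm = spec$geometry$diameter * 1e3,
        equilibrium_load_mN = cr$equilibrium_load * 1e3,
        creep_load_mN = cr$applied_load * 1e3),
        file.path(out_dir, paste0(sid, ".json")),
        auto_unbox = TRUE, digits = NA)

      truth <- rbind(truth, data.frame(
        specimen_id = sid, region = region, donor_id = donor,
        disc_level = lvl,
        H_A_MPa = spec$true_material$H_A / 1e6,
        k_e16 = spec$true_material$k / 1e-16,
        swelling_kPa = spec$true_swelling_pressure / 1e3,
        porosity = spec$true_porosity,
        thickness_mm = spec$geometry$thickness * 1e3,
        stringsAsFactors = FALSE))
      weights_df <- rbind(weights_df, data.frame(
        specimen_id = sid, W_wet_mg = w$W_wet, W_PBS_mg = w$W_PBS,
        W_dry_mg = w$W_dry, stringsAsFactors = FALSE))
    }
  }
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(weights_df, file.path(out_dir, "weights.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    master_seed = master_seed, n_per_region = as.list(n_per_region),
    quantize = quantize, extra_rms = extra_rms,
    balance_noise_mg = balance_noise_mg,
    n_resampled = total_resampled),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(truth)
}
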