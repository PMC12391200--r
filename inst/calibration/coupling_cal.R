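# one-off calibration of regional_priors()$latent_coupling
library(discmech)
pool_r <- function(lc, n = 300, seed0 = 1000) {
  pr <- regional_priors(latent_coupling = lc)
  regs <- rep(c("AF", "NP", "CEP"), length.out = n)
  H <- phi <- swp <- k <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample_specimen(regs[i], pr, seed = seed0 + i)
    H[i] <- s$true_material$H_A; phi[i] <- s$true_porosity
    swp[i] <- s$true_swelling_pressure; k[i] <- s$true_material$k
  }
  c(rH = cor(phi, H), rS = cor(phi, swp), rk = cor(phi, k))
}
for (lc in c(0.2, 0.3, 0.4, 0.5, 0.6))
  cat("lc =", lc, ":", round(pool_r(lc), 3), "\n")
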