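test_that("regional summaries match hand-computed values", {
  tab <- data.frame(region = rep(c("A", "B"), c(3, 2)),
                    y = c(1, 2, 3, 5, 5))
  s <- summarize_regions(tab, "y")
  a <- s[s$region == "A", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  # 95% CI: 2 +/- t(0.975, 2) / sqrt(3) = 2 +/- 2.4841
  expect_equal(a$ci_hi - a$mean, stats::qt(0.975, 2) / sqrt(3),
               tolerance = 1e-12)
  expect_equal(a$ci_hi - a$mean, 2.4841, tolerance = 1e-4)
  b <- s[s$region == "B", ]
  expect_equal(b$sd, 0)
  expect_equal(b$ci_hi, b$ci_lo)
  expect_error(summarize_regions(data.frame(region = "A", y = 1), "y"),
               ">= 2")
})

test_that("one-way ANOVA reproduces the long-hand decomposition", {
  # equal group means with within-group spread: F is exactly 0
  tab0 <- data.frame(region = rep(c("A", "B", "C"), each = 2),
                     y = c(1, 3, 2, 2, 0, 4))
  expect_equal(oneway_anova(tab0, "y")$F, 0)
  # seeded dataset against a spreadsheet-style computation
  set.seed(41)
  tab <- data.frame(region = rep(c("A", "B", "C"), c(5, 7, 6)),
                    y = rnorm(18, rep(c(1, 2, 4), c(5, 7, 6))))
  an <- oneway_anova(tab, "y")
  grand <- mean(tab$y)
  ssb <- ssw <- 0
  for (g in c("A", "B", "C")) {
    yg <- tab$y[tab$region == g]
    ssb <- ssb + length(yg) * (mean(yg) - grand)^2
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  expect_equal(an$ss_between, ssb, tolerance = 1e-12)
  expect_equal(an$ss_within, ssw, tolerance = 1e-12)
  expect_equal(an$F, (ssb / 2) / (ssw / 15), tolerance = 1e-12)
  expect_equal(an$p, stats::pf(an$F, 2, 15, lower.tail = FALSE))
  # two-group ANOVA equals the squared pooled t
  tab2 <- tab[tab$region != "C", ]
  tt <- stats::t.test(y ~ region, tab2, var.equal = TRUE)
  expect_equal(oneway_anova(tab2, "y")$F, unname(tt$statistic)^2,
               tolerance = 1e-12)
  expect_error(oneway_anova(data.frame(region = c("A", "A", "B", "B"),
                                       y = rep(2, 4)), "y"), "degenerate")
})

test_that("Holm step-down matches the hand example and p.adjust", {
  expect_equal(holm_adjust(0.02), 0.02)  # single comparison
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "holm"),
                 tolerance = 1e-14)
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("pairwise Welch tests agree with the base-R oracle", {
  set.seed(43)
  tab <- data.frame(region = rep(c("NP", "AF", "CEP"), c(10, 16, 8)),
                    y = rnorm(34, rep(c(0.44, 0.57, 1.19), c(10, 16, 8)),
                              0.4))
  pw <- pairwise_holm(tab, "y")
  expect_equal(nrow(pw), 3)
  for (j in 1:3) {
    regs <- strsplit(pw$pair[j], "-")[[1]]
    tt <- stats::t.test(tab$y[tab$region == regs[1]],
                        tab$y[tab$region == regs[2]])
    expect_equal(pw$p_raw[j], tt$p.value, tolerance = 1e-12)
    expect_equal(pw$df[j], unname(tt$parameter), tolerance = 1e-10)
  }
  expect_equal(pw$p_adj, holm_adjust(pw$p_raw))
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1.2, 2.8, 3.1, 4.7, 5.0)
  y <- c(2.0, 1.1, 4.4, 3.9, 6.2)
  pc <- pearson_corr(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pearson_corr(1:9, 2 * (1:9) + 1)$r, 1)
  set.seed(44)
  z <- rnorm(400); w <- rnorm(400)
  expect_lt(abs(pearson_corr(z, w)$r), 3 / sqrt(400))
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(1:2, 2:3), "n >= 3")
})

test_that("family-wise type-I error stays below 7% under the null", {
  # null generator: every region draws from the same (NP) parameter set
  pr <- regional_priors()
  pr$regions[, -1] <- pr$regions[rep(2, 3), -1]
  set.seed(2)
  rej <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    y <- c(
      vapply(1:16, function(i)
        sample_specimen("AF", pr, seed = r * 100 + i)$true_material$H_A,
        numeric(1)),
      vapply(1:10, function(i)
        sample_specimen("NP", pr, seed = r * 100 + 30 + i)$true_material$H_A,
        numeric(1)),
      vapply(1:10, function(i)
        sample_specimen("CEP", pr, seed = r * 100 + 60 + i)$true_material$H_A,
        numeric(1)))
    tab <- data.frame(region = rep(c("AF", "NP", "CEP"), c(16, 10, 10)),
                      y = y)
    if (any(pairwise_holm(tab, "y")$p_adj < 0.05)) rej <- rej + 1L
  }
  expect_lte(rej / n_rep, 0.07)
})

test_that("the configured CEP-NP stiffness gap is detectable", {
  # power check on the CEP-vs-NP family (n = 8 / 10): the Holm-adjusted
  # comparison should reject in a majority of 200 seeded replicates
  pr <- regional_priors()
  set.seed(1)
  hits <- 0L
  for (r in 1:200) {
    cep <- vapply(1:8, function(i)
      sample_specimen("CEP", pr, seed = r * 1000 + i)$true_material$H_A,
      numeric(1))
    np <- vapply(1:10, function(i)
      sample_specimen("NP", pr,
                      seed = r * 1000 + 100 + i)$true_material$H_A,
      numeric(1))
    tab <- data.frame(region = rep(c("CEP", "NP"), c(8, 10)),
                      y = c(cep, np) / 1e6)
    if (pairwise_holm(tab, "y")$p_adj[1] < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.5)
})

test_that("run_pipeline fails cleanly on bad input and is deterministic", {
  expect_error(run_pipeline(file.path(tempdir(), "no_such_dir")),
               "not found")
  empty <- withr::local_tempdir()
  expect_error(run_pipeline(empty), "no specimen")

  data_dir <- withr::local_tempdir()
  generate_cohort(data_dir, n_per_region = c(AF = 3, NP = 3, CEP = 3),
                  master_seed = 5)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(data_dir, out1))
  r2 <- suppressWarnings(run_pipeline(data_dir, out2))
  expect_identical(readBin(file.path(out1, "cohort.csv"), "raw", 1e6),
                   readBin(file.path(out2, "cohort.csv"), "raw", 1e6))
  expect_equal(nrow(r1$cohort), 9)
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "summary.md")))
  # a corrupt sidecar is reported as a failure, not an exception
  writeLines("{not json", file.path(data_dir, "XX_99.json"))
  r3 <- suppressWarnings(run_pipeline(data_dir))
  expect_equal(length(r3$failures), 1L)
  expect_equal(nrow(r3$cohort), 9)
})
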