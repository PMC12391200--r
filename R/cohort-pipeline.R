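#' Regional summary statistics
#'
#' Means, SDs and t-based 95% confidence intervals of one outcome per
#' region.
#'
#' @param table Cohort data frame with a `region` column.
#' @param outcome Name of the outcome column.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per region: `region`, `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_regions <- function(table, outcome, conf_level = 0.95) {
  stopifnot(is.data.frame(table), outcome %in% names(table),
            "region" %in% names(table))
  out <- NULL
  for (reg in unique(table$region)) {
    x <- table[[outcome]][table$region == reg]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2) stop("need >= 2 specimens in region ", reg)
    m <- mean(x); s <- stats::sd(x)
    hw <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
    out <- rbind(out, data.frame(region = reg, n = n, mean = m, sd = s,
                                 ci_lo = m - hw, ci_hi = m + hw,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within sum-of-squares decomposition over the region
#' factor, implemented directly.
#'
#' @inheritParams summarize_regions
#' @return List with `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`.
#' @export
oneway_anova <- function(table, outcome) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  keep <- is.finite(table[[outcome]])
  x <- table[[outcome]][keep]
  g <- factor(table$region[keep])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(tabulate(g) < 2)) stop("need >= 2 observations per group")
  grand <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((x - means[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(x) - nlevels(g)
  if (ss_w == 0 && ss_b == 0) stop("degenerate data: zero variance")
  Fv <- (ss_b / df1) / (ss_w / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_between = ss_b, ss_within = ss_w)
}

# Welch (unequal-variance) two-sample t, implemented directly
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  c(t = t, df = df, p = p)
}

#' Holm step-down adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity of the adjusted sequence and caps at 1.
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise Welch tests with Holm adjustment
#'
#' All region pairs compared by Welch's unequal-variance t-test with
#' Bonferroni-Holm adjusted p-values.
#'
#' @inheritParams summarize_regions
#' @return Data frame: `pair`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
pairwise_holm <- function(table, outcome) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  keep <- is.finite(table[[outcome]])
  regs <- unique(table$region[keep])
  if (length(regs) < 2) stop("need >= 2 regions")
  combs <- utils::combn(sort(regs), 2)
  res <- NULL
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    x <- table[[outcome]][keep & table$region == a]
    y <- table[[outcome]][keep & table$region == b]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 observations per region")
    w <- welch_t(x, y)
    res <- rbind(res, data.frame(pair = paste(a, b, sep = "-"),
                                 t = w["t"], df = w["df"], p_raw = w["p"],
                                 stringsAsFactors = FALSE, row.names = NULL))
  }
  res$p_adj <- holm_adjust(res$p_raw)
  res
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors (pairs with non-finite entries are dropped).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE), n = n)
}

#' Run the full cohort analysis pipeline
#'
#' Reads a dataset directory in the layout written by [generate_cohort()]
#' (creep CSV + JSON sidecar per specimen, pooled `weights.csv`), fits each
#' specimen with [fit_biphasic_creep()], computes porosity from the
#' weighings, and runs the regional statistics (summaries, one-way ANOVA,
#' Holm-adjusted pairwise Welch tests, pooled Pearson correlations against
#' porosity). The donor structure is recorded but no donor-level inference
#' is attempted: the statistics are fixed-effects only, a deliberate
#' simplification over donor random-intercept mixed models.
#'
#' @param data_dir Dataset directory.
#' @param out_dir Output directory (created if missing); receives
#'   `cohort.csv`, `report.json` and `summary.md`.
#' @param protocol A [load_protocol()].
#' @param alpha Significance threshold recorded in the report.
#' @return List with `cohort` (data frame), `report` (nested list) and
#'   `failures` (per-file error messages, empty on a clean run).
#' @export
run_pipeline <- function(data_dir, out_dir = NULL,
                         protocol = load_protocol(), alpha = 0.05) {
  if (!dir.exists(data_dir)) stop("data directory not found: ", data_dir)
  sidecars <- sort(list.files(data_dir, pattern = "\\.json$",
                              full.names = TRUE))
  sidecars <- sidecars[!grepl("manifest\\.json$", sidecars)]
  if (length(sidecars) == 0) stop("no specimen sidecars in ", data_dir)

  weights_path <- file.path(data_dir, "weights.csv")
  weights <- if (file.exists(weights_path))
    utils::read.csv(weights_path, stringsAsFactors = FALSE) else NULL

  cohort <- NULL
  failures <- list()
  for (js in sidecars) {
    csv <- sub("\\.json$", ".csv", js)
    rec <- tryCatch({
      tr <- read_creep_trace(csv, js)
      fit <- fit_biphasic_creep(tr, protocol)
      phi <- NA_real_
      if (!is.null(weights)) {
        wrow <- weights[weights$specimen_id == tr$specimen_id, ]
        if (nrow(wrow) == 1)
          phi <- porosity(buoyancy_weights(wrow$W_wet_mg, wrow$W_PBS_mg,
                                           wrow$W_dry_mg))
      }
      data.frame(specimen_id = tr$specimen_id, region = tr$region,
                 donor_id = as.character(tr$donor_id),
                 disc_level = as.character(tr$disc_level),
                 H_A_MPa = fit$H_A_MPa, k_e16 = fit$k_report,
                 swelling_kPa = fit$swelling_pressure / 1e3,
                 porosity = phi, r_squared = fit$r_squared,
                 rmse_um = fit$rmse * 1e6, converged = fit$converged,
                 duration_warning = fit$duration_warning,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[basename(js)]] <- conditionMessage(rec)
    } else {
      cohort <- rbind(cohort, rec)
    }
  }
  if (is.null(cohort)) stop("no specimen could be processed")

  outcomes <- c("H_A_MPa", "k_e16", "swelling_kPa")
  report <- list(
    method = paste("fixed-effects one-way ANOVA + Holm-adjusted pairwise",
                   "Welch tests (donor random effects not modeled)"),
    alpha = alpha, n_specimens = nrow(cohort),
    n_failures = length(failures))
  for (oc in outcomes) {
    blk <- list(summary = summarize_regions(cohort, oc),
                anova = oneway_anova(cohort, oc),
                pairwise = pairwise_holm(cohort, oc))
    if (any(is.finite(cohort$porosity)))
      blk$porosity_correlation <- pearson_corr(cohort$porosity, cohort[[oc]])
    report[[oc]] <- blk
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(format_report_md(report), file.path(out_dir, "summary.md"))
    if (length(failures))
      jsonlite::write_json(failures, file.path(out_dir, "failures.json"),
                           auto_unbox = TRUE)
  }
  list(cohort = cohort, report = report, failures = failures)
}

format_report_md <- function(report) {
  out <- c("# Regional biphasic cohort report", "",
           paste0("Method: ", report$method),
           sprintf("Specimens: %d (failures: %d), alpha = %g",
                   report$n_specimens, report$n_failures, report$alpha), "")
  for (oc in c("H_A_MPa", "k_e16", "swelling_kPa")) {
    blk <- report[[oc]]
    if (is.null(blk)) next
    out <- c(out, paste0("## ", oc), "")
    s <- blk$summary
    out <- c(out, "| region | n | mean | sd | 95% CI |",
             "|---|---|---|---|---|",
             sprintf("| %s | %d | %.3f | %.3f | [%.3f, %.3f] |",
                     s$region, s$n, s$mean, s$sd, s$ci_lo, s$ci_hi), "")
    out <- c(out, sprintf("ANOVA: F(%d, %d) = %.3f, p = %.4f", blk$anova$df1,
                          blk$anova$df2, blk$anova$F, blk$anova$p), "")
    pw <- blk$pairwise
    out <- c(out, "| pair | t | df | p raw | p Holm |", "|---|---|---|---|---|",
             sprintf("| %s | %.3f | %.1f | %.4f | %.4f |",
                     pw$pair, pw$t, pw$df, pw$p_raw, pw$p_adj), "")
    if (!is.null(blk$porosity_correlation)) {
      pc <- blk$porosity_correlation
      out <- c(out, sprintf(
        "Pooled Pearson correlation with porosity: r = %.2f, p = %.4f, n = %d",
        pc$r, pc$p, pc$n), "")
    }
  }
  out
}
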