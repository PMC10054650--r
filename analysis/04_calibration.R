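#!/usr/bin/env Rscript
# Simulation calibration of the whole pipeline at the study's problem
# sizes: (a) LC50 parameter recovery and Fieller coverage over 500
# simulated assays at the reference truth (LC50 171 ng/mL, slope 1.85,
# 6-dose 1:2 series, 12 larvae/well, 3 replicates); (b) synergism-factor
# calibration over 200 simulated 1:1 mixtures under the no-interaction
# null (s = 1) and at the published synergy level (s = 11.44).
# Writes results/calibration.csv.

suppressPackageStartupMessages(library(quantalmix))

seed <- 20230211
tm <- true_model(slope = 1.85, lc50 = 171)
des <- assay_design(c1 = choose_c1(tm), larvae_range = c(12, 12))

## (a) parameter recovery and interval coverage -------------------------
res <- vapply(derive_seeds(seed, 500), function(s) {
  fit <- tryCatch(fit_quantal(simulate_assay(des, tm, seed = s)),
                  error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_, NA_real_))
  lc <- tryCatch(confidence_limits(fit, method = "fieller"),
                 error = function(e) NULL)
  if (is.null(lc)) c(lc_p(fit)$estimate, NA, NA)
  else c(lc$estimate, lc$lower, lc$upper)
}, numeric(3))
med <- median(res[1, ], na.rm = TRUE)
coverage <- mean(res[2, ] <= 171 & res[3, ] >= 171, na.rm = TRUE)
cat(sprintf("parameter recovery over 500 assays: median LC50 %.1f ng/mL (truth 171, rel. error %.1f%%)\n",
            med, 100 * abs(med - 171) / 171))
cat(sprintf("empirical coverage of 95%% Fieller limits: %.3f\n", coverage))

## (b) synergism-factor calibration --------------------------------------
comps <- mixture_components(c("A", "B"), c(0.5, 0.5), c(171, 228))
one_sf <- function(s_assay, s) {
  tmA <- true_model(slope = 1.85, lc50 = 171)
  tmB <- true_model(slope = 1.85, lc50 = 228)
  tmM <- true_model(slope = 1.85,
                    lc50 = expected_lc50_ssa(comps)$expected / s)
  sds <- derive_seeds(s_assay, 3)
  desF <- function(t) assay_design(c1 = choose_c1(t),
                                   larvae_range = c(12, 12))
  fA <- fit_quantal(simulate_assay(desF(tmA), tmA, sds[1]))
  fB <- fit_quantal(simulate_assay(desF(tmB), tmB, sds[2]))
  fM <- fit_quantal(simulate_mixture_assay(desF(tmM), comps,
                                           reference_slope = 1.85, s = s,
                                           seed = sds[3]))
  est <- mixture_components(c("A", "B"), c(0.5, 0.5),
                            c(lc_p(fA)$estimate, lc_p(fB)$estimate))
  synergism_factor(expected_lc50_ssa(est)$expected, lc_p(fM)$estimate)
}
sf_null <- vapply(derive_seeds(seed + 1, 200), one_sf, numeric(1), s = 1)
sf_syn <- vapply(derive_seeds(seed + 2, 200), one_sf, numeric(1), s = 11.44)
cat(sprintf("SSA null (s = 1): mean SF %.3f (MC SE %.3f) over 200 mixtures\n",
            mean(sf_null), sd(sf_null) / sqrt(200)))
cat(sprintf("synergy recovery (s = 11.44): median SF %.2f (rel. error %.1f%%)\n",
            median(sf_syn), 100 * abs(median(sf_syn) - 11.44) / 11.44))

out <- data.frame(
  quantity = c("median LC50 estimate (truth 171)",
               "coverage of 95% Fieller limits",
               "mean SF under SSA null (s = 1)",
               "MC SE of mean SF under null",
               "median SF at s = 11.44"),
  value = c(med, coverage, mean(sf_null), sd(sf_null) / sqrt(200),
            median(sf_syn))
)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/calibration.csv", row.names = FALSE)
cat("wrote results/calibration.csv\n")
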