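#!/usr/bin/env Rscript
# Generate the demo bioassay data set: single-toxin serial-dilution assays
# shaped like the published study (6 concentrations in 1:2 steps, 10-15
# larvae per well, 3 replicate wells, untreated controls), two proteins
# with no activity up to 1e5 ng/mL, and two 1:1 mixture treatments -- one
# synergistic pair of active toxins and one "enabling" pair of
# individually non-active proteins. Writes the well-level data and the
# mixture definitions under results/.

suppressPackageStartupMessages(library(quantalmix))

seed <- 20230211
dir.create("results", showWarnings = FALSE)

# single toxins: published slope and LC50, dose series anchored at the
# published top doses
singles <- list(
  Cry4Aa  = list(slope = 1.80, lc50 = 178, c1 = 1000),
  Cry4Ba  = list(slope = 1.17, lc50 = 46,  c1 = 500),
  Cry11Aa = list(slope = 1.11, lc50 = 228, c1 = 2500),
  Cyt1Aa  = list(slope = 1.85, lc50 = 171, c1 = 1000)
)
# non-active proteins: no measurable kill up to the 1e5 ng/mL screen dose
inerts <- c("Cyt1A-like", "Cry56A-like")

seeds <- derive_seeds(seed, length(singles) + length(inerts) + 2)
parts <- list()
i <- 0

for (trt in names(singles)) {
  s <- singles[[trt]]
  des <- assay_design(c1 = s$c1, larvae_range = c(10, 15))
  tm <- true_model(slope = s$slope, lc50 = s$lc50)
  i <- i + 1
  parts[[trt]] <- simulate_assay(des, tm, seed = seeds[i], treatment = trt)
  cat(sprintf("simulated %-12s true LC50 %7.1f ng/mL, top dose %g\n",
              trt, s$lc50, s$c1))
}

for (trt in inerts) {
  des <- assay_design(c1 = 1e5, larvae_range = c(10, 15))
  tm <- true_model(slope = 1.85, lc50 = 1e9)   # far beyond the top dose
  i <- i + 1
  parts[[trt]] <- simulate_assay(des, tm, seed = seeds[i], treatment = trt)
  cat(sprintf("simulated %-12s non-active up to %g ng/mL\n", trt, 1e5))
}

# synergistic mixture: Cyt1Aa + Cry11Aa at the published synergy level
comps_syn <- mixture_components(c("Cyt1Aa", "Cry11Aa"), c(0.5, 0.5),
                                c(171, 228))
s_syn <- 11.44
tm_mix <- true_model(slope = 2.37,
                     lc50 = expected_lc50_ssa(comps_syn)$expected / s_syn)
i <- i + 1
parts[["Cyt1Aa+Cry11Aa"]] <- simulate_mixture_assay(
  assay_design(c1 = choose_c1(tm_mix), larvae_range = c(10, 15)),
  comps_syn, reference_slope = 2.37, s = s_syn, seed = seeds[i],
  treatment = "Cyt1Aa+Cry11Aa")
cat(sprintf("simulated Cyt1Aa+Cry11Aa with synergy multiplier %.2f (true LC50 %.1f)\n",
            s_syn, tm_mix$lc50))

# enabling mixture: both components individually non-active, the mixture
# itself lethal at the published level
tm_en <- true_model(slope = 1.59, lc50 = 186)
i <- i + 1
parts[["Cyt1A-like+Cry56A-like"]] <- simulate_assay(
  assay_design(c1 = choose_c1(tm_en), larvae_range = c(10, 15)),
  tm_en, seed = seeds[i], treatment = "Cyt1A-like+Cry56A-like")
cat("simulated Cyt1A-like+Cry56A-like (enabling pair, true LC50 186)\n")

all_obs <- validate_bioassay(do.call(rbind, lapply(parts, as.data.frame)))
write_bioassay(all_obs, "results/simulated_bioassays.csv")

mix_def <- data.frame(
  mixture = rep(c("Cyt1Aa+Cry11Aa", "Cyt1A-like+Cry56A-like"), each = 2),
  component = c("Cyt1Aa", "Cry11Aa", "Cyt1A-like", "Cry56A-like"),
  proportion = 0.5,
  treatment_ref = c("Cyt1Aa", "Cry11Aa", "Cyt1A-like", "Cry56A-like")
)
write.csv(mix_def, "results/mixture_definitions.csv", row.names = FALSE,
          quote = FALSE)

cat(sprintf("\nwrote %d wells for %d treatments to results/simulated_bioassays.csv (seed %d)\n",
            nrow(all_obs), length(parts), seed))
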