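#!/usr/bin/env Rscript
# Build the synthetic longitudinal study cohort: four diagnostic-group
# analogs (CN, MCI-S, MCI-C, AD) of 12 subjects each, two timepoints per
# subject on a level-4 grid with 3T-like scan noise, follow-ups resampled
# onto their own rotated/jittered grids. Writes the cohort to GIFTI under
# scratch/ and a per-group summary of the imposed ground truth to results/.

library(cortexshift)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cohort <- generate_cohort(n_per_group = 12,
                          effect_scales = c(CN = 0, MCIS = 0.3,
                                            MCIC = 0.8, AD = 1),
                          noise = noise_spec("3T"), level = 4L, seed = seed)
write_cohort_dir(cohort, "scratch/cohort_3T")

truth_summary <- do.call(rbind, lapply(cohort, function(s) {
  msk <- s$cortex
  data.frame(subject_id = s$id, group = s$group, effect = s$effect,
             truth_mean_area_log2 = mean(s$truth$area[msk]),
             truth_mean_thickness_log2 = mean(s$truth$thickness[msk]),
             truth_peak_area_log2 = min(s$truth$area[msk]))
}))
write.table(truth_summary, "results/simulated_cohort.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

agg <- aggregate(cbind(truth_mean_area_log2, truth_mean_thickness_log2) ~
                   group, truth_summary, mean)
cat("Simulated cohort written to scratch/cohort_3T (48 subjects).\n")
cat("Group-mean true log2 changes (area / thickness):\n")
print(agg, row.names = FALSE)
cat("CN carries no systematic atrophy; effect magnitude rises",
    "MCIS < MCIC < AD with lognormal subject heterogeneity.\n")
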