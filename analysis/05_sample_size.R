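#!/usr/bin/env Rscript
# Sample-size experiment: nested subsets of 12/24/48/90 subjects per group
# (affected vs control) under noisier 1.5T-like scans, scoring map-level
# detection power (any FWE-significant vertex inside the true atrophy
# patch) and false positives outside it, per measure.

library(cortexshift)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)

pow <- run_samplesize_experiment(sample_sizes = c(12L, 24L, 48L, 90L),
                                 replicates = 12, effect_scale = 0.5,
                                 level = 3, n_permutations = 500,
                                 seed = seed)
write.table(pow, "results/sample_size_power.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Detection power by per-group sample size and measure:\n")
print(reshape(pow[, c("n", "metric", "power")], idvar = "n",
              timevar = "metric", direction = "wide"), row.names = FALSE)
cat("\nFalse-positive (outside true region) rates:\n")
print(reshape(pow[, c("n", "metric", "fp_rate")], idvar = "n",
              timevar = "metric", direction = "wide"), row.names = FALSE)
cat("\nPower should rise with n; volume change, which pools the thickness",
    "and area signals, should be the most sensitive at every n.\n")
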