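#!/usr/bin/env Rscript
# Group morphometry on the study cohort: vertex-wise change maps, global
# percent losses with ANOVA/Tukey/Cohen's d, ROI changes with MANOVA and
# Bonferroni pairwise tests, and permutation-FWE vertex-wise inference
# (per-group one-sample atrophy tests and all pairwise contrasts).
# The cohort is generated on a shared grid (known correspondence), so this
# script exercises the measurement and inference stages at full cohort
# scale; registration itself is validated in 02_validate_registration.R.

library(cortexshift)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(n_per_group = 12,
                          effect_scales = c(CN = 0, MCIS = 0.3,
                                            MCIC = 0.8, AD = 1),
                          noise = noise_spec("3T"), level = 3L,
                          seed = seed, reparam = FALSE)
pipe <- run_pipeline(cohort, "known", n_permutations = 500, seed = seed)

num <- vapply(pipe$global, is.numeric, logical(1))
pipe$global[num] <- lapply(pipe$global[num], signif, 6)
write.table(pipe$global, "results/global_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
roi_out <- pipe$roi
num <- vapply(roi_out, is.numeric, logical(1))
roi_out[num] <- lapply(roi_out[num], signif, 5)
write.table(roi_out, "results/roi_changes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Global percent losses by group (means):\n")
print(aggregate(cbind(pct_thickness_loss, pct_area_loss, pct_volume_loss) ~
                  group, pipe$global, mean), row.names = FALSE)

glb <- lapply(c("pct_thickness_loss", "pct_area_loss", "pct_volume_loss"),
              function(mtr) {
                r <- global_anova_tukey(pipe$global[[mtr]], pipe$global$group)
                r$pairwise$measure <- mtr
                r$pairwise
              })
glb <- do.call(rbind, glb)
write.table(glb, "results/global_anova_tukey.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nLargest pairwise effects (|d|), global measures:\n")
print(head(glb[order(-abs(glb$d)), c("measure", "pair", "p_adj", "d")], 6),
      row.names = FALSE)

roi_tests <- lapply(c("d_thick_log2", "d_area_log2", "d_vol_log2"),
                    function(mtr) {
                      r <- roi_group_tests(pipe$roi, mtr)
                      data.frame(measure = mtr, r$manova)
                    })
roi_tests <- do.call(rbind, roi_tests)
write.table(roi_tests, "results/roi_manova.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nROI MANOVA (Pillai) per measure:\n")
print(roi_tests, row.names = FALSE)

sig_counts <- do.call(rbind, lapply(names(pipe$one_sample), function(nm) {
  p <- as.numeric(pipe$one_sample[[nm]]$fwe_p)
  data.frame(test = nm, n_sig_vertices = sum(p <= 0.05 & pipe$mask))
}))
sig_pair <- do.call(rbind, lapply(names(pipe$pairwise), function(nm) {
  p <- as.numeric(pipe$pairwise[[nm]]$fwe_p)
  data.frame(test = nm, n_sig_vertices = sum(p <= 0.05 & pipe$mask))
}))
vertexwise <- rbind(sig_counts, sig_pair)
write.table(vertexwise, "results/vertexwise_significance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nFWE-significant vertex counts (alpha = 0.05):\n")
print(vertexwise, row.names = FALSE)
cat("\nExpected pattern: no CN detections; detections grow MCIS < MCIC < AD;",
    "volume change is the most sensitive measure.\n")
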