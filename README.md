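# cortexshift

Longitudinal cortical atrophy mapping on triangulated cortical surfaces:
anatomically constrained spherical registration for vertex-wise
surface-area change, thickness/volume change maps, and permutation-based
group inference with TFCE and family-wise error correction — validated
end-to-end on synthetic cortical surfaces with known ground-truth atrophy.

## Who this is for

Researchers measuring structural brain change between two MRI timepoints
(e.g. cognitively normal vs MCI vs Alzheimer's disease cohorts) who want
the tangential (surface-area) component of atrophy alongside cortical
thickness, and a self-contained simulation framework to validate and
calibrate such a pipeline without access-restricted scan data.

## The method

For each subject with baseline and follow-up surfaces and thickness maps
(CT1, CT2), the pipeline computes per vertex

    Δthick  = log2(CT2 / CT1)          (CT smoothed 20 mm FWHM per timepoint)
    Δarea   = log2(SA2 / SA1)          (SA = 1/3 of incident triangle areas)
    Δvolume = Δthick_smoothed + Δarea  (log2 additivity, exact)

SA2 comes from registration: the input sphere is warped coarse-to-fine
over icosphere control grids to match a sulcal-depth feature, regularized
by a strain energy on the **anatomical** surfaces with density

    W = c_shear (R/2 − 1) + c_bulk (J + 1/J − 2),
    J = λ1 λ2,  R = λ1/λ2 + λ2/λ1,

(λ1, λ2 = principal stretches per triangle). Both directions are
registered and averaged to cancel direction bias. Group inference:
one-sample t (per-group atrophy), pairwise t / ANOVA F between groups,
TFCE enhancement (H = 2, E = 1, area-weighted extent), and FWE p-values
from the permutation distribution of the maximum enhanced statistic
(sign flips or label permutations; identity always included). Global
measures get ANOVA + Tukey HSD + Cohen's d; ROI measures get MANOVA
(Pillai) + Bonferroni pairwise tests.

The synthetic-cortex generator produces folded star-shaped surfaces with
known material deformation (a geodesic atrophy patch plus global change),
smooth scanner noise at "3T-like"/"1.5T-like" levels, and follow-ups
sampled on independent rotated grids — ground truth is measured from the
known correspondence, never assumed.

## Worked example

```r
library(cortexshift)

# one synthetic AD-analog subject, two timepoints, regridded follow-up
sub <- generate_subject("demo", "AD", effect_scale = 1, level = 4, seed = 11)
reg <- register_bidirectional(sub, control_levels = 2:3)
maps <- compute_change_maps(sub, reg)

mean(as.numeric(reg$area_change)[sub$cortex], na.rm = TRUE)
#> [1] -0.01279269
mean(sub$truth$area[sub$cortex])
#> [1] -0.01198027
cor(as.numeric(reg$area_change)[sub$cortex], sub$truth$area[sub$cortex])
#> [1] 0.7670368
```

The recovered map mean (−0.0128 log2 units ≈ 0.9% areal loss over the
interval) matches the subject's true mean atrophy (−0.0120), and the
vertex-wise map correlates 0.77 with the ground truth for a single scan
pair at 3T-like noise; cohort-mean maps (the scale at which area change is
interpreted) correlate above 0.9.

The full study is organized as numbered drivers:

```sh
Rscript analysis/01_simulate.R            # 4-group cohort with ground truth
Rscript analysis/02_validate_registration.R
Rscript analysis/03_group_morphometry.R   # global/ROI/vertex-wise stats
Rscript analysis/04_field_strength.R      # 3T-like vs 1.5T-like consistency
Rscript analysis/05_sample_size.R         # power at n = 12/24/48/90
Rscript analysis/06_null_calibration.R    # FWE calibration under the null
```

Each writes its tables under `results/` and prints what it found.

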