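---
title: "Measuring longitudinal cortical atrophy with anatomically constrained spherical registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal cortical atrophy with anatomically constrained spherical registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexshift)
```

## The measurement problem

Longitudinal structural MRI yields, per subject, a cortical surface
reconstruction and a thickness map at each of two timepoints. Cortical
*thickness* change can be read off vertex-wise once the two scans are in
correspondence, but cortical *surface-area* change — the tangential
component of atrophy — requires a registration that tracks how each
triangle of the baseline surface deforms into the follow-up surface. This
package implements that pipeline: spherical surface registration whose
deformation penalty (a strain energy) is evaluated on the *anatomical*
surfaces rather than on the parameter spheres, vertex-wise log2 change
maps for thickness, area and volume, and permutation-based group
inference with threshold-free cluster enhancement (TFCE) and family-wise
error (FWE) correction.

Real scan data for such a study is access-restricted and its registrations
take days per subject, so the package pairs the pipeline with a
synthetic-cortex generator that produces longitudinal subjects with known
ground truth. All empirical statements below are the ones the test suite
and `scripts/acceptance.R` recompute.

## Change measures

With per-vertex thickness `CT1`, `CT2` and vertex surface areas `SA1`,
`SA2` at the two timepoints, the measures are

* thickness change: `log2(CT2 / CT1)`,
* surface-area change: `log2(SA2 / SA1)`,
* volume change: `log2((SA2 * CT2) / (SA1 * CT1))`.

Vertex area attributes one third of every incident triangle's area to each
of its corners, so vertex areas sum exactly to the mesh area (asserted to
1e-12 relative). Thickness maps are smoothed with a 20 mm FWHM geodesic
Gaussian kernel *per timepoint* before the ratio; volume change is defined
as smoothed-thickness change plus **unsmoothed** area change, which makes
the log2 additivity identity exact by construction at every vertex, at ROI
level, and globally. Global summaries use the unweighted vertex mean for
thickness and the vertex-area sum for area (an area-weighted mean is
available as an option); percent loss is `(baseline - followup) /
baseline * 100`, so `(1 - volLoss) = (1 - thickLoss) * (1 - areaLoss)`
exactly. The medial wall (one designated parcel) is excluded from every
statistic.

Smoothing uses truncated (3 sigma) geodesic-distance Gaussian weights with
per-vertex normalization: constants are preserved exactly and the output
obeys the max principle. Geodesic distance is the shortest path along mesh
edges — adequate because the kernel scale (20 mm) is far above the mesh
edge length; exact polyhedral geodesics are out of scope.

## Registration

Each surface carries a spherical parameterization (for synthetic subjects,
from the generator; for external data a companion sphere file). A
registration warps the input sphere so that a sulcal-depth feature — the
z-scored signed radial deviation from the best-fit sphere — matches the
reference's feature, while penalizing physical deformation between the
anatomical surfaces. For each triangle the in-plane affine map to its
image has principal stretches λ1, λ2, and the energy density is

W = c_shear (R/2 − 1) + c_bulk (J + 1/J − 2),  J = λ1 λ2,  R = λ1/λ2 + λ2/λ1.

W is non-negative, zero exactly at isometries, invariant to rigid motion,
and symmetric in J ↔ 1/J for pure dilation. In `anatomical` mode (the
default) the image points live on the reference *anatomical* surface; in
`spherical` mode (the comparator) strain is computed between the parameter
spheres. On strongly folded synthetic surfaces the anatomical mode tracks
true area change with consistently lower error than the spherical mode
(`analysis/02_validate_registration.R`).

The warp is parameterized by displacements of a coarse-to-fine series of
icosphere control grids (levels 2–4 by default; a level-5 icosphere has
10,242 vertices, the resolution at which area change is usually reported).
Optimization is projected gradient descent in the control vertices'
tangent planes with backtracking line search; steps that fold a control
triangle or fail to decrease the objective are rejected with step halving,
so accepted iterations are monotone. A global rotation is estimated first
(Nelder–Mead on the rotation vector against the feature similarity alone)
because scan pairs share no native orientation. Both directions
(baseline→follow-up and follow-up→baseline) are registered; the reverse
map is resampled onto the baseline grid through the forward correspondence
and the two are averaged (reverse negated) to cancel direction bias.

Area change from a correspondence integrates the image of each baseline
face on the reference surface with one level of midpoint supersampling
(corners and warped edge-midpoints re-sampled on the reference surface),
then applies the 1/3-attribution rule to both timepoints. Map-level
recovery is summarized on cohort-mean maps: a single scan pair's area map
at 3-mm face resolution is noise-limited (scan noise and regridding enter
at face scale), and area maps are scientifically interpreted at group
level, never per subject per vertex.

Defaults that matter: `c_shear = 1`, `c_bulk = 1`, `lambda_reg = 1`
(strain per unit area against mean squared feature mismatch; chosen by
recovery error on synthetic validation cohorts — lower values let the warp
chase feature noise, inflating local Jacobian error), per-level
convergence tolerance 1e-4, at most 100 accepted iterations per level.
For level-4 (2,562-vertex) data the experiments use control levels 2–3;
the finest (level-4) control grid adds degrees of freedom at the scale of
the measurement noise without improving recovery.

## Group inference

Vertex-wise statistics are the one-sample t (per-group atrophy; one-tailed
for loss by default), the two-sample pooled-variance t (pairwise group
contrasts; two-tailed), and the one-way ANOVA F. Maps are enhanced with
TFCE, `TFCE(v) = Σ_h e(h,v)^E h^H dh`, where the extent `e` is the total
vertex area of the edge-connected suprathreshold component containing `v`.
`H = 2`, `E = 1`, 100 integration steps follow the surface-data
convention; the implementation (an incremental union-find over descending
thresholds, in C++) is tested against a brute-force integration to 1%
on dense steps. FWE correction uses the permutation distribution of the
maximum enhanced statistic over the cortex mask: sign flips of subject
maps for one-sample tests, group-label permutations otherwise, identity
always included, so `fwe_p ∈ [1/P, 1]` and p is monotone in the enhanced
statistic. Exhaustive enumeration replaces sampling when there are at most
4,096 sign patterns or 10,000 two-group assignments. Calibration is
checked empirically: 200 zero-effect cohorts reject at a rate inside the
95% binomial interval around α = 0.05.

Global measures get one-way ANOVA with Tukey HSD pairwise comparisons and
Cohen's d (pooled SD); ROI measures get one-way MANOVA (Pillai's trace,
via `stats::manova`) per measure and per-ROI pairwise t tests with
Bonferroni correction (factor = ROIs × group pairs).

## The synthetic cohort: what it emulates, and what it does not

A subject is a *pseudocortex*: an icosphere (radius 80 mm, so the sphere
area is in the range of a hemisphere midthickness surface) deformed
radially by a smooth band-limited random field (sum of random plane waves;
default amplitude 6% of the radius, 25 mm correlation length). Radial
deformation of a star-shaped surface cannot self-intersect, and the folds
both create the matching feature and keep the surface resolvable at the
mesh scale. Baseline thickness is a smooth field centered on 2.5 mm,
clamped to 1–4.5 mm.

Atrophy is imposed as a material deformation: inside a circular geodesic
patch (default radius 50°, peak log2 area change −0.12, peak log2
thickness change −0.12, plus a −0.01 global component) vertices slide
toward the patch center under a radially symmetric angular remap whose
induced sphere-map area scale equals the target field *exactly*; the
angular deficit is released smoothly over an annulus out to 1.5× the
patch radius, so the deformation is local with a mild compensating
expansion ring. Because the anatomical folds ride along with the material,
the realized anatomical area change differs slightly from the sphere-map
target; ground truth is therefore *measured* from the known one-to-one
correspondence of the clean surfaces, never assumed, and truth volume
change is truth area + truth thickness change by definition. These peak
values are order-of-magnitude choices for a 2-year interval in a
symptomatic group — the study this design emulates reports no per-region
rates usable as simulation defaults — and group severity scales them
(CN 0, MCI-S 0.3, MCI-C 0.8, AD 1.0) with a lognormal per-subject factor
(σ_log = 0.3).

Scanner noise is spatially smooth (12 mm correlation), not i.i.d.:
geometry noise displaces the surface radially — the star-shaped analog of
boundary-placement error along the surface normal — with SD 0.12 mm, and
thickness error is an independent field with SD 0.12 mm. The "1.5T-like"
preset doubles both SDs. The follow-up scan is sampled on its own grid:
the standard grid rotated by 5° about a random axis plus 0.05° per-vertex
tangential jitter, evaluating the analytic deformed surface exactly at the
new directions (a real scanner samples the true anatomy, not an
interpolation of the baseline mesh). Re-generating a subject with the same
anatomy seed under a new noise seed yields the same true atrophy with
independent noise — the basis of the field-strength experiment.

Not emulated: biophysically realistic gyrification, hemispheric asymmetry,
intensity-level MRI artifacts, demographic covariates, and a real gyral
atlas (the 20 icosahedron-base-face parcels stand in structurally for DK
ROIs, one parcel — the farthest from the atrophy patch — acting as the
medial wall). Passing tests therefore show the pipeline is correct and
calibrated under smooth, star-shaped geometry with known correspondence;
they do not certify performance on real segmentations, whose error
structure is richer.

## Experiments and problem sizes

The analysis drivers run at sizes chosen to keep a full desktop run in
minutes while leaving the conclusions stable across seeds:

* registration validation (`02`): 12 subjects, level-4 (2,562-vertex)
  grids, bidirectional registration with control levels 2–3;
* group morphometry (`03`): 4 groups × 12 subjects, level-3 grids, 500
  permutations;
* scan-quality consistency (`04`): 12 subjects re-generated at 3T-like
  and 1.5T-like noise, level 3;
* sample size (`05`): nested 12 ⊂ 24 ⊂ 48 ⊂ 90 per group, 12 replicate
  cohorts, 1.5T-like noise, effect scale 0.5 (the weaker-contrast analog
  of a noisier large cohort), map-level power at FWE α = 0.05;
* null calibration (`06`): 200 zero-effect cohorts, 12 per group, 500
  permutations.

The consistency, power and variance experiments measure change maps
through the known-correspondence route (the same formulas, geometry and
noise realized on the mesh, with the registration optimization bypassed):
registration accuracy is established separately in `02`, and coupling 200
calibration replicates or 180-subject cohorts to hour-scale registration
would add runtime, not information.

Predicted and observed orderings: area-change maps are more consistent
across scan quality than (even smoothed) thickness-change maps, because
smooth geometric noise perturbs local area only through its gradient
while thickness error enters the thickness ratio directly; within-subject
spatial variance of area change is below that of smoothed thickness
change for the same reason; and volume change, which pools two partially
independent signals, is the most sensitive measure at every sample size.

## Numerical choices and degenerate inputs

* Barycentric point location on a sphere grid: greedy nearest-vertex
  ascent on the adjacency graph (exact on convex triangulations), then a
  gnomonic barycentric test of the incident faces, with an exhaustive
  fallback for queries outside the one-ring; weights are clamped to be
  non-negative and renormalized.
* Collapsed image triangles in the strain energy (numerical J ≤ 0) get a
  large finite penalty and a flag rather than infinities.
* Zero-variance vertices in t/F maps are set to 0 and flagged.
* Degenerate (zero-area) faces warn and contribute zero area; isolated
  vertices get zero vertex area with a warning.
* A near-spherical surface has no matching feature; `compute_feature`
  warns and returns zeros, and registration then reduces to its strain
  prior.
* Boundary vertices of the toy parcellation are assigned to the
  lowest-numbered adjacent parcel.

## Known limitations

* The optimizer is first-order descent on a non-convex objective; it
  recovers smooth, moderate deformations (the regime of 2-year atrophy)
  but is not a substitute for discrete-search registration frameworks on
  large or convoluted warps.
* Per-subject, per-vertex area change at 3-mm face scale is noise-limited;
  recovery guarantees are stated at cohort-map level.
* Graph geodesics overestimate distances by a few percent on coarse
  meshes, slightly widening the effective smoothing kernel.
* TFCE integrates extent from the lowest thresholds, where suprathreshold
  sets percolate; in the presence of strong true clusters this can lift
  weakly elevated vertices far from the signal above the permutation
  maximum. The sample-size experiment therefore reports the
  out-of-region detection fraction as a diagnostic rather than holding it
  to the family-wise alpha, which applies under the full null (and is
  verified there by the calibration experiment).
* The sphere-sampled GIFTI support covers ASCII and (gzipped) base64
  float/int arrays, not external binary files.
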