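#' Generate one longitudinal synthetic subject
#'
#' A subject is a folded pseudocortex with a smooth baseline thickness map
#' (centered on 2.5 mm, clamped to 1-4.5 mm), a follow-up produced by
#' [apply_atrophy()] at the subject's effect magnitude, and independent
#' smooth scanner noise on each of the two scans. The structural
#' parcellation supplies the cortex/medial-wall masks; the wall ROI is
#' chosen as the ROI farthest from the atrophy patch center. With
#' `reparam = TRUE` the follow-up is resampled onto a rotated, jittered
#' grid so that registration is nontrivial, as for real scan pairs.
#'
#' @param id subject identifier.
#' @param group diagnostic-group label.
#' @param effect_scale group-level effect multiplier (0 = no systematic
#'   atrophy, the cognitively-normal analog).
#' @param spec an `atrophy_spec`.
#' @param noise a `noise_spec`.
#' @param level icosphere level of the subject grid.
#' @param radius,bumpiness,fold_scale pseudocortex parameters.
#' @param subject_sdlog SD of the lognormal subject-severity factor.
#' @param reparam resample the follow-up onto its own grid.
#' @param rotation,jitter_sd_deg passed to [reparameterize()].
#' @param seed integer; the subject is a pure function of its arguments.
#'   Drives the anatomy, baseline thickness and subject severity factor.
#' @param noise_seed integer driving the scan noise and follow-up regridding
#'   only; defaults to a value derived from `seed`. Re-generating a subject
#'   with the same `seed` but a new `noise_seed` yields the same true
#'   atrophy under independent scanner noise.
#' @return a `subject_record`: list with `id`, `group`, `effect`,
#'   `baseline`/`followup` (each `mesh` + `thickness`), `truth` (per-vertex
#'   log2 `area`/`thickness`/`volume` change on the baseline grid),
#'   `parcellation`, `wall_roi`, `cortex` (baseline-grid mask),
#'   `cortex_followup`.
#' @export
generate_subject <- function(id, group, effect_scale,
                             spec = atrophy_spec(),
                             noise = noise_spec("3T"),
                             level = 4L, radius = 80, bumpiness = 0.06,
                             fold_scale = 25, subject_sdlog = 0.3,
                             reparam = TRUE, rotation = 5,
                             jitter_sd_deg = 0.05, seed = 1L,
                             noise_seed = NULL) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 10L, 4L))
  if (is.null(noise_seed)) noise_seed <- seeds[4]
  nseeds <- with_seed(noise_seed, sample.int(.Machine$integer.max - 10L, 3L))
  base <- make_pseudocortex(level, radius, bumpiness, fold_scale,
                            seed = seeds[1])
  tfield <- sphere_field(25, radius, n_waves = 40L, seed = seeds[2])
  thickness_fn <- function(d)
    pmin(pmax(2.5 + 0.6 * eval_sphere_field(tfield, d), 1), 4.5)
  thick <- thickness_fn(base$sphere)
  effect <- if (effect_scale == 0) 0 else
    effect_scale * with_seed(seeds[3], exp(stats::rnorm(1, 0, subject_sdlog)))
  fu <- apply_atrophy(base, thick, spec, noise, effect, seed = nseeds[1],
                      thickness_fn = thickness_fn)
  bl <- apply_noise(base, thick, noise, nseeds[2])
  parc <- build_parcellation(base)
  wall <- farthest_roi(base, parc, spec$center)
  ctx <- as.logical(cortex_mask(parc, wall))
  ctx_fu <- ctx
  fmesh <- fu$mesh
  if (reparam) {
    # the scan has its own grid: sample the analytic follow-up surface at a
    # rotated, jittered set of directions (exactly, not by interpolation)
    grid <- make_icosphere(level, 1)
    p <- sample_directions(grid$sphere, rotation, jitter_sd_deg, nseeds[3])
    fmesh <- surface_mesh(fu$analytic$point(p), grid$faces,
                          name = paste0(base$name, ".fu.regrid"),
                          sphere = grid$sphere, validate = FALSE)
    fmesh$ico <- grid$ico
    fu$thickness <- fu$analytic$thickness(p)
    d0 <- fu$analytic$orig_dir(p)
    nn <- nearest_vertex(base$sphere, d0, mesh_edge_list(base))
    ctx_fu <- ctx[nn]
  }
  structure(list(id = id, group = group, effect = effect,
                 baseline = list(mesh = bl$mesh, thickness = bl$thickness),
                 followup = list(mesh = fmesh, thickness = fu$thickness),
                 truth = fu$truth, parcellation = parc, wall_roi = wall,
                 cortex = ctx, cortex_followup = ctx_fu,
                 reparam_seed = nseeds[3]),
            class = "subject_record")
}

farthest_roi <- function(mesh, parc, center) {
  dirs <- mesh$sphere
  cen <- vapply(seq_along(parc$roi_names), function(r) {
    d <- colMeans(dirs[parc$labels == r, , drop = FALSE])
    sum((d / sqrt(sum(d^2))) * center)
  }, numeric(1))
  which.min(cen)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("subject_record %s [%s]: effect %.3f, %d vertices\n", x$id,
              x$group, x$effect, n_vertices(x$baseline$mesh)))
  invisible(x)
}

#' Generate a longitudinal cohort with known ground truth
#'
#' Subjects are generated per diagnostic group with group-specific effect
#' scales times a lognormal per-subject severity factor, independent scan
#' noise throughout, and deterministic derivation of all per-subject seeds
#' from the cohort seed. The atrophy field itself (patch location, peak
#' change) is shared; only its magnitude varies by group and subject, so a
#' zero effect scale gives the exchangeable null cohort.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param effect_scales named numeric vector: group label -> effect scale.
#' @param noise a `noise_spec`.
#' @param spec an `atrophy_spec`.
#' @param level icosphere level.
#' @param seed cohort seed.
#' @param atrophy_seed optional separate seed stream for anatomy/atrophy;
#'   lets the same subjects be re-generated under different noise (the
#'   field-strength experiment).
#' @param ... further arguments to [generate_subject()].
#' @return list of `subject_record` (class `cohort`).
#' @export
generate_cohort <- function(n_per_group = 12L,
                            effect_scales = c(CN = 0, MCIS = 0.3,
                                              MCIC = 0.8, AD = 1),
                            noise = noise_spec("3T"),
                            spec = atrophy_spec(), level = 4L,
                            seed = 1L, atrophy_seed = NULL, ...) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  groups <- names(effect_scales)
  if (is.null(groups)) stop("effect_scales must be named by group")
  n <- n_per_group * length(groups)
  if (is.null(atrophy_seed)) atrophy_seed <- seed
  subject_seeds <- with_seed(atrophy_seed,
                             sample.int(.Machine$integer.max - 10L, n))
  noise_seeds <- with_seed(seed + 1L,
                           sample.int(.Machine$integer.max - 10L, n))
  subs <- vector("list", n)
  k <- 0L
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      subs[[k]] <- generate_subject(
        id = sprintf("%s_%02d", g, i), group = g,
        effect_scale = effect_scales[[g]], spec = spec, noise = noise,
        level = level, seed = subject_seeds[k],
        noise_seed = noise_seeds[k], ...)
    }
  }
  structure(subs, class = "cohort")
}
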