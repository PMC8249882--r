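#' Run the full measurement + inference pipeline on a cohort
#'
#' For every subject: obtain the baseline-grid change maps (either through
#' bidirectional registration, or through the known shared-grid
#' correspondence for synthetic cohorts generated without regridding), then
#' run the group statistics: per-group one-sample tests of atrophy
#' (one-tailed, loss < 0) and all pairwise group contrasts (two-tailed),
#' each permutation-FWE corrected on TFCE-enhanced maps, for the smoothed
#' thickness, surface-area and volume change. Subjects whose registration
#' fails are excluded and reported. Deterministic given the scheme seed.
#'
#' @param cohort list of `subject_record`.
#' @param measurement "known" (shared-grid correspondence) or "register"
#'   (bidirectional registration; required when follow-ups were regridded).
#' @param params `strain_params` for registration.
#' @param control_levels control-grid levels for registration.
#' @param smoothing `smoothing_params` for thickness maps.
#' @param n_permutations permutations per test.
#' @param seed seed for permutation sampling.
#' @param tests which map-level tests to run ("one_sample", "pairwise").
#' @param cache_dir optional directory for per-subject results: completed
#'   subjects are saved there and re-used on a re-run, so an interrupted
#'   cohort resumes where it stopped.
#' @param run_stats set FALSE to return only maps/tables.
#' @param verbose print per-subject progress.
#' @return list: `maps` (per-subject `change_maps`), `metrics` (list of
#'   subjects x vertices matrices: thickness, area, volume), `global`
#'   (per-subject global summary table), `roi` (ROI change table),
#'   `one_sample` (per group x metric `stat_report`), `pairwise` (per
#'   group-pair x metric), `mask`, `excluded`.
#' @export
run_pipeline <- function(cohort, measurement = c("known", "register"),
                         params = strain_params(), control_levels = 2:3,
                         smoothing = smoothing_params(),
                         n_permutations = 500L, seed = 1L,
                         tests = c("one_sample", "pairwise"),
                         cache_dir = NULL, run_stats = TRUE,
                         verbose = FALSE) {
  measurement <- match.arg(measurement)
  tests <- match.arg(tests, several.ok = TRUE)
  if (!is.null(cache_dir))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  maps <- vector("list", length(cohort))
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(sub$id, ".maps.rds")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      maps[[i]] <- readRDS(cache_file)
      if (verbose) message(sub$id, ": restored from cache")
      next
    }
    reg <- NULL
    if (measurement == "register") {
      reg <- register_bidirectional(sub, params,
                                    control_levels = control_levels)
      if (reg$failed) {
        excluded <- c(excluded, sub$id)
        if (verbose) message(sub$id, ": registration failed, excluded")
        next
      }
    }
    maps[[i]] <- compute_change_maps(sub, reg, smoothing)
    if (!is.null(cache_file)) saveRDS(maps[[i]], cache_file)
    if (verbose) message(sub$id, ": maps done")
  }
  keep <- !vapply(maps, is.null, logical(1))
  cohort <- cohort[keep]
  maps <- maps[keep]
  mask <- maps[[1]]$mask
  stack <- function(field)
    do.call(rbind, lapply(maps, function(m) {
      x <- as.numeric(m[[field]])
      x[is.na(x)] <- 0
      x
    }))
  metrics <- list(thickness = stack("thickness_change_smoothed"),
                  area = stack("area_change"),
                  volume = stack("volume_change"))
  global <- do.call(rbind, lapply(cohort, global_summary))
  roi <- roi_change_table(cohort, maps)
  groups <- vapply(cohort, function(s) s$group, character(1))
  out <- list(maps = maps, metrics = metrics, global = global, roi = roi,
              mask = mask, groups = groups, excluded = excluded)
  if (!run_stats) return(out)
  mesh <- cohort[[1]]$baseline$mesh
  edges <- mesh_edge_list(mesh)
  areas <- as.numeric(vertex_areas(mesh))
  glev <- unique(groups)
  one_sample <- list()
  if ("one_sample" %in% tests) for (g in glev) {
    for (mname in names(metrics)) {
      Mg <- metrics[[mname]][groups == g, , drop = FALSE]
      one_sample[[paste(g, mname, sep = ".")]] <-
        permutation_fwe(Mg, mesh, test = "one_sample", tail = "left",
                        scheme = permutation_scheme("sign_flip",
                                                    n_permutations, seed),
                        mask = mask, edges = edges, areas = areas)
    }
  }
  pairwise <- list()
  if ("pairwise" %in% tests && length(glev) >= 2) {
    prs <- utils::combn(glev, 2)
    for (k in seq_len(ncol(prs))) {
      sel <- groups %in% prs[, k]
      for (mname in names(metrics)) {
        pairwise[[paste(prs[1, k], prs[2, k], mname, sep = ".")]] <-
          permutation_fwe(metrics[[mname]][sel, , drop = FALSE], mesh,
                          groups = groups[sel], test = "two_sample",
                          tail = "two",
                          scheme = permutation_scheme("label_permutation",
                                                      n_permutations, seed),
                          mask = mask, edges = edges, areas = areas)
      }
    }
  }
  out$one_sample <- one_sample
  out$pairwise <- pairwise
  out
}

#' Cross-noise-level consistency of change maps
#'
#' The same subjects (same anatomy and true atrophy) are re-generated under
#' two scanner-noise levels with independent noise, standing in for
#' matched scan pairs at two field strengths; per subject and measure, the
#' Pearson correlation between the two resulting change maps over the
#' cortex is computed. Higher correlation = measurement less impacted by
#' scan quality.
#'
#' @param n_subjects number of subjects (one atrophic group).
#' @param noise_levels list of two `noise_spec`.
#' @param effect_scale group effect scale of the subjects.
#' @param level icosphere level.
#' @param seed integer seed.
#' @param smoothing `smoothing_params`.
#' @return list: `per_subject` data.frame (subject, thickness, area,
#'   volume correlations), `median` named vector.
#' @export
run_noise_experiment <- function(n_subjects = 10L,
                                 noise_levels = list(noise_spec("3T"),
                                                     noise_spec("1.5T")),
                                 effect_scale = 1, level = 3L, seed = 1L,
                                 smoothing = smoothing_params()) {
  stopifnot(length(noise_levels) == 2)
  cohorts <- lapply(seq_along(noise_levels), function(k)
    generate_cohort(n_per_group = n_subjects,
                    effect_scales = c(G = effect_scale),
                    noise = noise_levels[[k]], level = level,
                    seed = seed + k, atrophy_seed = seed,
                    reparam = FALSE))
  rows <- lapply(seq_len(n_subjects), function(i) {
    m1 <- compute_change_maps(cohorts[[1]][[i]], NULL, smoothing)
    m2 <- compute_change_maps(cohorts[[2]][[i]], NULL, smoothing)
    msk <- m1$mask
    cc <- function(f) stats::cor(as.numeric(m1[[f]])[msk],
                                 as.numeric(m2[[f]])[msk])
    data.frame(subject = cohorts[[1]][[i]]$id,
               thickness = cc("thickness_change_smoothed"),
               area = cc("area_change"), volume = cc("volume_change"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_subject = per,
       median = c(thickness = stats::median(per$thickness),
                  area = stats::median(per$area),
                  volume = stats::median(per$volume)))
}

# Inside = the atrophy patch proper. Outside = far from every deformed
# region: the compensating expansion annulus (to 1.5x the radius) carries
# real signal, and its edge smears by a face width with TFCE extending
# clusters across it, so false positives are scored beyond twice the
# patch radius.
true_region_mask <- function(mesh, spec, mask, profile_cutoff = 0.05,
                             buffer = 2) {
  theta <- acos(pmin(1, pmax(-1, as.numeric(mesh$sphere %*% spec$center))))
  inside <- patch_profile(theta, spec$radius) > profile_cutoff
  list(inside = inside & mask,
       outside = (theta > buffer * spec$radius) & mask)
}

#' Detection power versus sample size
#'
#' Two-group simulation analog of subsampling a large cohort: per
#' replicate, an affected group and a control group of `max(sample_sizes)`
#' subjects each are generated, nested subsets of each sample size are
#' compared (two-sample permutation test with TFCE + FWE per measure), and
#' detection is scored at the map level: power = fraction of replicates
#' with at least one significant vertex (fwe_p <= alpha) inside the true
#' atrophy patch; the false-positive rate counts replicates with a
#' significant vertex outside it.
#'
#' @param sample_sizes per-group sizes, subsets nested within the largest.
#' @param replicates number of replicate cohorts.
#' @param effect_scale effect scale of the affected group.
#' @param noise a `noise_spec` (default the noisier 1.5T-like analog).
#' @param level icosphere level.
#' @param n_permutations permutations per test.
#' @param alpha FWE significance level.
#' @param seed integer seed.
#' @return data.frame: n, metric, power, fp_rate, replicates.
#' @export
run_samplesize_experiment <- function(sample_sizes = c(12L, 24L, 48L, 90L),
                                      replicates = 8L, effect_scale = 0.5,
                                      noise = noise_spec("1.5T"),
                                      level = 3L, n_permutations = 500L,
                                      alpha = 0.05, seed = 1L,
                                      smoothing = smoothing_params()) {
  nmax <- max(sample_sizes)
  # patch-only atrophy: the region away from the patch then carries no true
  # signal, so detections there are genuine false positives
  spec <- atrophy_spec(global_log2_area = 0, global_log2_thickness = 0)
  hits <- array(0, dim = c(length(sample_sizes), 3, 2),
                dimnames = list(sample_sizes,
                                c("thickness", "area", "volume"),
                                c("inside", "outside")))
  for (r in seq_len(replicates)) {
    cohort <- generate_cohort(n_per_group = nmax,
                              effect_scales = c(CN = 0, AD = effect_scale),
                              noise = noise, spec = spec, level = level,
                              seed = seed + 7919L * r, reparam = FALSE)
    groups <- vapply(cohort, function(s) s$group, character(1))
    maps <- lapply(cohort, compute_change_maps, registration = NULL,
                   smoothing = smoothing)
    mask <- maps[[1]]$mask
    mesh <- cohort[[1]]$baseline$mesh
    edges <- mesh_edge_list(mesh)
    areas <- as.numeric(vertex_areas(mesh))
    region <- true_region_mask(mesh, spec, mask)
    stack <- function(field)
      do.call(rbind, lapply(maps, function(m) {
        x <- as.numeric(m[[field]]); x[is.na(x)] <- 0; x
      }))
    metrics <- list(thickness = stack("thickness_change_smoothed"),
                    area = stack("area_change"),
                    volume = stack("volume_change"))
    for (si in seq_along(sample_sizes)) {
      nn <- sample_sizes[si]
      sel <- c(which(groups == "CN")[seq_len(nn)],
               which(groups == "AD")[seq_len(nn)])
      for (mi in seq_along(metrics)) {
        rep_seed <- (seed + 104729L * r + 13L * si) %% 2000000000L
        res <- permutation_fwe(metrics[[mi]][sel, , drop = FALSE], mesh,
                               groups = groups[sel], test = "two_sample",
                               tail = "two",
                               scheme = permutation_scheme(
                                 "label_permutation", n_permutations,
                                 rep_seed),
                               mask = mask, edges = edges, areas = areas)
        sig <- as.numeric(res$fwe_p) <= alpha
        hits[si, mi, "inside"] <- hits[si, mi, "inside"] +
          any(sig[region$inside])
        hits[si, mi, "outside"] <- hits[si, mi, "outside"] +
          any(sig[region$outside])
      }
    }
  }
  out <- expand.grid(n = sample_sizes,
                     metric = c("thickness", "area", "volume"),
                     stringsAsFactors = FALSE)
  out$power <- mapply(function(n, m)
    hits[as.character(n), m, "inside"] / replicates, out$n, out$metric)
  out$fp_rate <- mapply(function(n, m)
    hits[as.character(n), m, "outside"] / replicates, out$n, out$metric)
  out$replicates <- replicates
  out
}

#' Registration recovery of known atrophy
#'
#' Validation experiment for the registration pipeline: a cohort with known
#' ground truth is generated (follow-ups regridded, so registration is
#' required), each subject is registered bidirectionally, and the recovered
#' log2 area-change maps are compared with the truth. `"shrinkage"` imposes
#' a uniform 10% areal loss (log2 0.9 everywhere); `"patch"` uses the
#' default localized atrophy spec. Map-level agreement is summarized on the
#' cohort mean maps (the scale at which area change is interpreted; single
#' scan-pair maps are noise-limited at vertex resolution) along with
#' per-subject map means and errors.
#'
#' @param what "shrinkage" or "patch".
#' @param n_subjects cohort size.
#' @param level icosphere level.
#' @param noise a `noise_spec`.
#' @param params `strain_params` for registration.
#' @param control_levels control-grid levels.
#' @param seed integer seed.
#' @return list: `map_means` (per subject), `median_map_mean`,
#'   `mean_truth_mean`, `cor_mean_map` (cohort-mean recovered vs truth),
#'   `mae_mean_map`, `per_subject_cor`, `per_subject_mae`, `failed`.
#' @export
run_recovery_experiment <- function(what = c("shrinkage", "patch"),
                                    n_subjects = 12L, level = 4L,
                                    noise = noise_spec("3T"),
                                    params = strain_params(),
                                    control_levels = 2:3, seed = 1L) {
  what <- match.arg(what)
  spec <- if (what == "shrinkage")
    atrophy_spec(c(0, 0, 1), 50, 0, 0, global_log2_area = log2(0.9),
                 global_log2_thickness = 0)
  else atrophy_spec()
  sdlog <- if (what == "shrinkage") 0 else 0.3
  cohort <- generate_cohort(n_subjects, c(G = 1), noise = noise,
                            spec = spec, level = level, seed = seed,
                            subject_sdlog = sdlog)
  rec <- list(); tru <- list(); mm <- c(); cors <- c(); maes <- c()
  failed <- character(0)
  msk <- NULL
  for (sub in cohort) {
    reg <- register_bidirectional(sub, params,
                                  control_levels = control_levels)
    if (reg$failed) {
      failed <- c(failed, sub$id)
      next
    }
    if (is.null(msk)) msk <- sub$cortex
    r <- as.numeric(reg$area_change)
    r[is.na(r)] <- 0
    rec[[length(rec) + 1L]] <- r
    tru[[length(tru) + 1L]] <- sub$truth$area
    mm <- c(mm, mean(r[msk]))
    cors <- c(cors, stats::cor(r[msk], sub$truth$area[msk]))
    maes <- c(maes, mean(abs(r - sub$truth$area)[msk]))
  }
  mrec <- Reduce(`+`, rec) / length(rec)
  mtru <- Reduce(`+`, tru) / length(tru)
  list(map_means = mm, median_map_mean = stats::median(mm),
       mean_truth_mean = mean(vapply(tru, function(t) mean(t[msk]),
                                     numeric(1))),
       cor_mean_map = stats::cor(mrec[msk], mtru[msk]),
       mae_mean_map = mean(abs(mrec - mtru)[msk]),
       per_subject_cor = cors, per_subject_mae = maes, failed = failed)
}

#' Family-wise error calibration under the null
#'
#' Generates zero-effect two-group cohorts (exchangeable by construction),
#' runs the two-sample permutation-FWE test on each replicate's change
#' maps, and records whether any vertex is declared significant at `alpha`.
#' For a valid procedure the rejection rate should match `alpha` up to
#' binomial error.
#'
#' @param replicates number of null cohorts.
#' @param n_per_group subjects per group.
#' @param level icosphere level.
#' @param n_permutations permutations per test.
#' @param metric which change measure to test.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list: `rejections` logical per replicate, `rate`, `min_p` per
#'   replicate.
#' @export
run_null_calibration <- function(replicates = 200L, n_per_group = 12L,
                                 level = 3L, n_permutations = 500L,
                                 metric = "volume", alpha = 0.05,
                                 seed = 1L,
                                 smoothing = smoothing_params()) {
  rej <- logical(replicates)
  minp <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cohort <- generate_cohort(n_per_group = n_per_group,
                              effect_scales = c(A = 0, B = 0),
                              noise = noise_spec("3T"), level = level,
                              seed = seed + 7919L * r, reparam = FALSE)
    groups <- vapply(cohort, function(s) s$group, character(1))
    maps <- lapply(cohort, compute_change_maps, registration = NULL,
                   smoothing = smoothing)
    mask <- maps[[1]]$mask
    mesh <- cohort[[1]]$baseline$mesh
    field <- switch(metric, thickness = "thickness_change_smoothed",
                    area = "area_change", volume = "volume_change")
    M <- do.call(rbind, lapply(maps, function(m) {
      x <- as.numeric(m[[field]]); x[is.na(x)] <- 0; x
    }))
    res <- permutation_fwe(M, mesh, groups = groups, test = "two_sample",
                           tail = "two",
                           scheme = permutation_scheme(
                             "label_permutation", n_permutations,
                             (seed + 104729L * r) %% 2000000000L),
                           mask = mask)
    minp[r] <- min(as.numeric(res$fwe_p)[mask])
    rej[r] <- minp[r] <= alpha
  }
  list(rejections = rej, rate = mean(rej), min_p = minp)
}
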