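#' Vertex-wise log2 change between two timepoint maps
#'
#' @param before,after strictly positive per-vertex values (e.g. thickness
#'   or vertex area at baseline and follow-up).
#' @param mask cortex mask; vertices outside it are NA in the result.
#' @return `metric_map` of log2(after/before); nonpositive inputs are
#'   masked to NA with a warning.
#' @export
log2_change <- function(before, after, mask = NULL) {
  mask <- as_mask(mask, length(before))
  bad <- mask & (before <= 0 | after <= 0)
  if (any(bad)) warning("nonpositive values masked out of log2 change")
  out <- rep(NA_real_, length(before))
  ok <- mask & !bad
  out[ok] <- log2(after[ok] / before[ok])
  nm <- if (inherits(before, "metric_map")) attr(before, "mesh_name") else "mesh"
  metric_map(out, nm, "log2-ratio")
}

#' Vertex-wise change maps for one subject
#'
#' Produces the four standard maps on the baseline grid: unsmoothed and
#' smoothed log2 thickness change, log2 surface-area change, and log2
#' volume change. Follow-up thickness is transferred to the baseline grid
#' through the forward registration correspondence (or taken directly when
#' the two timepoints share a vertex grid and `registration` is NULL, as
#' for synthetic subjects with known correspondence). The two timepoint
#' thickness maps are smoothed separately before the ratio (20 mm FWHM
#' default); volume change is smoothed thickness change plus *unsmoothed*
#' area change, so the log2 additivity identity holds exactly.
#'
#' @param subject a `subject_record`.
#' @param registration optional `registration_result`; NULL uses the known
#'   shared-grid correspondence.
#' @param smoothing a `smoothing_params`.
#' @param smooth_what `"timepoints"` smooths CT1 and CT2 separately before
#'   the ratio; `"ratio"` smooths the log-ratio instead.
#' @param S optional precomputed smoothing matrix for the baseline mesh.
#' @return a `change_maps` list: `thickness_change`,
#'   `thickness_change_smoothed`, `area_change`, `volume_change` (all
#'   `metric_map` on the baseline grid, NA off-cortex), plus `ct1`, `ct2`
#'   (baseline-grid thickness at the two timepoints) and `mask`.
#' @export
compute_change_maps <- function(subject, registration = NULL,
                                smoothing = smoothing_params(),
                                smooth_what = c("timepoints", "ratio"),
                                S = NULL) {
  smooth_what <- match.arg(smooth_what)
  b <- subject$baseline$mesh
  f <- subject$followup$mesh
  mask <- as_mask(subject$cortex, n_vertices(b))
  ct1 <- as.numeric(subject$baseline$thickness)
  if (!is.null(registration)) {
    if (registration$failed) stop("registration failed for this subject")
    f_loc <- precompute_locator(f$sphere, f$faces)
    hit <- list(face = registration$forward$face, w = registration$forward$w)
    ct2 <- interp_at(f_loc, hit, as.numeric(subject$followup$thickness))
    area_change <- as.numeric(registration$area_change)
  } else {
    if (n_vertices(b) != n_vertices(f))
      stop("no registration and timepoints do not share a grid")
    ct2 <- as.numeric(subject$followup$thickness)
    area_change <- log2(as.numeric(vertex_areas(f)) /
                        as.numeric(vertex_areas(b)))
  }
  if (is.null(S)) S <- smoothing_matrix(b, smoothing, mask)
  raw <- log2_change(ct1, ct2, mask)
  if (smooth_what == "timepoints") {
    s1 <- smooth_metric(ct1, b, smoothing, mask, S)
    s2 <- smooth_metric(ct2, b, smoothing, mask, S)
    smoothed <- log2_change(s1, s2, mask)
  } else {
    sm <- raw
    sm[!mask] <- 0
    smoothed <- smooth_metric(as.numeric(sm), b, smoothing, mask, S)
    smoothed[!mask] <- NA_real_
    smoothed <- metric_map(smoothed, b$name, "log2-ratio")
  }
  ac <- area_change
  ac[!mask] <- NA_real_
  vol <- as.numeric(smoothed) + ac
  structure(list(thickness_change = raw,
                 thickness_change_smoothed = smoothed,
                 area_change = metric_map(ac, b$name, "log2-ratio"),
                 volume_change = metric_map(vol, b$name, "log2-ratio"),
                 ct1 = ct1, ct2 = ct2, mask = mask),
            class = "change_maps")
}

#' Global percent-loss summary for one subject
#'
#' Global thickness is the unweighted mean over cortex vertices, global
#' surface area the vertex-area sum, and volume their product, at each
#' timepoint on its own grid; percent loss is (baseline - followup) /
#' baseline * 100, so (1 - volume loss) = (1 - thickness loss) x
#' (1 - area loss) holds exactly.
#'
#' @param subject a `subject_record`.
#' @return one-row data.frame: subject_id, group, the six global measures
#'   and pct_thickness_loss, pct_area_loss, pct_volume_loss.
#' @export
global_summary <- function(subject) {
  b <- subject$baseline$mesh
  f <- subject$followup$mesh
  mb <- as_mask(subject$cortex, n_vertices(b))
  mf <- as_mask(subject$cortex_followup, n_vertices(f))
  t1 <- mean_thickness(subject$baseline$thickness, mb)
  t2 <- mean_thickness(subject$followup$thickness, mf)
  a1 <- total_area(b, mb)
  a2 <- total_area(f, mf)
  v1 <- t1 * a1
  v2 <- t2 * a2
  data.frame(subject_id = subject$id %||% "subject",
             group = subject$group %||% NA_character_,
             thickness_bl = t1, thickness_fu = t2,
             area_bl = a1, area_fu = a2, volume_bl = v1, volume_fu = v2,
             pct_thickness_loss = (t1 - t2) / t1 * 100,
             pct_area_loss = (a1 - a2) / a1 * 100,
             pct_volume_loss = (v1 - v2) / v1 * 100,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intrasubject variance of the change maps
#'
#' Spatial variability of each measure within a subject: the variance
#' (square of the across-vertex standard deviation, computed with the
#' population 1/n convention) of the smoothed-thickness, surface-area and
#' volume change maps over the cortex mask.
#'
#' @param maps a `change_maps`.
#' @param mask optional mask overriding the one in `maps`.
#' @return named numeric: `thickness`, `area`, `volume`.
#' @export
intrasubject_variance <- function(maps, mask = NULL) {
  mask <- if (is.null(mask)) maps$mask else as_mask(mask, length(maps$mask))
  popvar <- function(x) {
    x <- x[mask & !is.na(x)]
    mean((x - mean(x))^2)
  }
  c(thickness = popvar(as.numeric(maps$thickness_change_smoothed)),
    area = popvar(as.numeric(maps$area_change)),
    volume = popvar(as.numeric(maps$volume_change)))
}

#' Per-ROI change table for a cohort
#'
#' Within each ROI of the subject's parcellation (the medial-wall ROI
#' excluded): unweighted mean thickness and total vertex area at both
#' timepoints on the baseline grid (follow-up area attributed through the
#' area-change map), then log2 changes; per-ROI volume change is the sum of
#' the thickness and area changes, as at the vertex level.
#'
#' @param cohort list of `subject_record`.
#' @param maps list of `change_maps`, one per subject (same order).
#' @return data.frame: subject_id, group, roi, n_vertices, d_thick_log2,
#'   d_area_log2, d_vol_log2.
#' @export
roi_change_table <- function(cohort, maps) {
  stopifnot(length(cohort) == length(maps))
  rows <- list()
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    mp <- maps[[i]]
    parc <- sub$parcellation
    va1 <- as.numeric(vertex_areas(sub$baseline$mesh))
    va2 <- va1 * 2^ifelse(is.na(as.numeric(mp$area_change)), 0,
                          as.numeric(mp$area_change))
    rois <- setdiff(sort(unique(parc$labels)), sub$wall_roi)
    for (r in rois) {
      in_roi <- parc$labels == r & mp$mask
      if (!any(in_roi)) {
        warning(sprintf("ROI %d has no cortex vertices; dropped", r))
        next
      }
      t1 <- mean(mp$ct1[in_roi])
      t2 <- mean(mp$ct2[in_roi])
      a1 <- sum(va1[in_roi])
      a2 <- sum(va2[in_roi])
      dth <- log2(t2 / t1)
      dar <- log2(a2 / a1)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sub$id, group = sub$group, roi = r,
                   n_vertices = sum(in_roi), d_thick_log2 = dth,
                   d_area_log2 = dar, d_vol_log2 = dth + dar,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
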