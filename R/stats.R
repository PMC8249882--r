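#' TFCE parameters
#'
#' Height and extent exponents and integration step for threshold-free
#' cluster enhancement. H = 2, E = 1 with 100 integration steps follow the
#' usual convention for surface data; the step is dh = max(statistic) /
#' n_steps unless `dh` is given explicitly.
#'
#' @param H height exponent (>= 0).
#' @param E extent exponent (>= 0).
#' @param n_steps number of integration steps.
#' @param dh explicit step height (overrides `n_steps` spacing).
#' @export
tfce_params <- function(H = 2, E = 1, n_steps = 100L, dh = NULL) {
  if (H < 0 || E < 0) stop("H and E must be >= 0")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  structure(list(H = H, E = E, n_steps = as.integer(n_steps), dh = dh),
            class = "tfce_params")
}

tfce_one_side <- function(values, edges, areas, params) {
  mx <- max(values)
  if (mx <= 0) return(numeric(length(values)))
  dh <- if (is.null(params$dh)) mx / params$n_steps else params$dh
  thresholds <- rev(seq(dh, mx + dh * 1e-9, by = dh))
  tfce_pos_cpp(values, edges, areas, params$H, params$E, thresholds, dh)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' TFCE(v) = sum over thresholds h of extent(h, v)^E * h^H * dh, where
#' extent is the total vertex area of the edge-connected suprathreshold
#' component containing v at height h. Negative values are enhanced on the
#' negated map separately and re-negated. Vertices outside the mask are
#' removed from the graph (value and extent 0).
#'
#' @param stat_map per-vertex statistic.
#' @param mesh a `surface_mesh` (used for edges and vertex areas unless
#'   given explicitly).
#' @param params a `tfce_params`.
#' @param mask cortex mask.
#' @param edges optional precomputed 2-column edge matrix.
#' @param areas optional per-vertex areas used as extent weights.
#' @return `metric_map` of enhanced values (signed like the input).
#' @export
tfce_enhance <- function(stat_map, mesh = NULL, params = tfce_params(),
                         mask = NULL, edges = NULL, areas = NULL) {
  x <- as.numeric(stat_map)
  if (is.null(edges)) edges <- mesh_edge_list(mesh)
  if (is.null(areas)) areas <- as.numeric(vertex_areas(mesh))
  mask <- as_mask(mask, length(x))
  x[!mask | is.na(x)] <- 0
  pos <- pmax(x, 0)
  neg <- pmax(-x, 0)
  out <- tfce_one_side(pos, edges, areas, params)
  if (any(neg > 0)) out <- out - tfce_one_side(neg, edges, areas, params)
  metric_map(out, if (is.null(mesh)) "mesh" else mesh$name, "statistic")
}

#' Vertex-wise one-sample t map
#'
#' t = mean / (sd / sqrt(n)) per vertex across subjects. Zero-variance
#' vertices get t = 0 and are recorded in attribute `"flagged"`.
#'
#' @param M subjects x vertices matrix of change maps.
#' @param mask cortex mask (off-mask vertices get 0).
#' @return `metric_map` of t values.
#' @export
one_sample_t_map <- function(M, mask = NULL) {
  n <- nrow(M)
  if (n < 2) stop("need at least 2 subjects")
  mask <- as_mask(mask, ncol(M))
  m <- colMeans(M)
  v <- (colSums(M^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  flag <- v <= 1e-24
  t <- ifelse(flag, 0, m / sqrt(v / n))
  t[!mask] <- 0
  out <- metric_map(t, units = "statistic")
  attr(out, "flagged") <- which(flag & mask)
  out
}

#' Vertex-wise one-way ANOVA F map
#'
#' F = MS_between / MS_within per vertex. Vertices with zero within-group
#' variance are flagged and set to 0.
#'
#' @param M subjects x vertices matrix.
#' @param groups factor/character of group labels, length nrow(M).
#' @param mask cortex mask.
#' @return `metric_map` of F values.
#' @export
anova_f_map <- function(M, groups, mask = NULL) {
  groups <- as.factor(groups)
  n <- nrow(M)
  g <- nlevels(groups)
  if (g < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with n >= 2 each")
  mask <- as_mask(mask, ncol(M))
  G <- stats::model.matrix(~ groups - 1)
  ng <- colSums(G)
  gs <- crossprod(G, M) # g x V group sums
  gm <- gs / ng
  m <- colMeans(M)
  ssb <- colSums(ng * (gm - rep(m, each = g))^2)
  sst <- colSums(M^2) - n * m^2
  ssw <- pmax(sst - ssb, 0)
  flag <- ssw <= 1e-24
  f <- ifelse(flag, 0, (ssb / (g - 1)) / (ssw / (n - g)))
  f[!mask] <- 0
  out <- metric_map(f, units = "statistic")
  attr(out, "flagged") <- which(flag & mask)
  out
}

#' Permutation scheme
#'
#' @param kind "sign_flip" (one-sample) or "label_permutation" (group
#'   comparisons).
#' @param n_permutations number of permutations including the identity,
#'   which is always the first.
#' @param seed integer RNG seed for sampled permutations.
#' @param exhaustive NULL = enumerate all permutations automatically when
#'   feasible (2^n <= 4096 sign flips, or <= 10,000 two-group label
#'   assignments); TRUE/FALSE to force.
#' @export
permutation_scheme <- function(kind = c("sign_flip", "label_permutation"),
                               n_permutations = 1000L, seed = 1L,
                               exhaustive = NULL) {
  kind <- match.arg(kind)
  if (is.null(exhaustive) || !exhaustive) {
    if (n_permutations < 100 && !isTRUE(exhaustive))
      stop("n_permutations must be >= 100 (or exhaustive)")
  }
  structure(list(kind = kind, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), exhaustive = exhaustive),
            class = "permutation_scheme")
}

sign_flip_matrix <- function(n, scheme) {
  total <- 2^n
  exhaustive <- if (is.null(scheme$exhaustive)) total <= 4096 else
    scheme$exhaustive
  if (total < 20) stop("too few subjects for >= 20 distinct permutations")
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    # put the identity (all +1) first
    id <- which(rowSums(S) == n)
    S <- rbind(S[id, , drop = FALSE], S[-id, , drop = FALSE])
  } else {
    S <- with_seed(scheme$seed,
                   matrix(sample(c(1, -1), (scheme$n_permutations - 1) * n,
                                 replace = TRUE), ncol = n))
    S <- rbind(rep(1, n), S)
  }
  unname(S)
}

label_perm_matrix <- function(groups, scheme) {
  groups <- as.factor(groups)
  n <- length(groups)
  tab <- table(groups)
  total <- exp(lgamma(n + 1) - sum(lgamma(tab + 1)))
  if (total < 20) stop("too few subjects for >= 20 distinct permutations")
  exhaustive <- if (is.null(scheme$exhaustive))
    nlevels(groups) == 2 && total <= 10000 else scheme$exhaustive
  if (exhaustive) {
    if (nlevels(groups) != 2)
      stop("exhaustive label permutation implemented for 2 groups only")
    n1 <- tab[[1]]
    cmb <- utils::combn(n, n1)
    P <- matrix(2L, ncol(cmb), n)
    for (i in seq_len(ncol(cmb))) P[i, cmb[, i]] <- 1L
    id <- which(apply(P, 1, function(r)
      all((r == 1L) == (groups == levels(groups)[1]))))
    P <- rbind(P[id, , drop = FALSE], P[-id, , drop = FALSE])
  } else {
    P <- matrix(0L, scheme$n_permutations, n)
    P[1, ] <- as.integer(groups)
    with_seed(scheme$seed, {
      for (i in 2:scheme$n_permutations)
        P[i, ] <- as.integer(groups)[sample.int(n)]
    })
  }
  unname(P)
}

#' Permutation-based FWE-corrected vertex-wise inference
#'
#' PALM-style max-statistic permutation inference on TFCE-enhanced maps:
#' the observed statistic map (one-sample t, two-group t, or one-way F) is
#' enhanced with TFCE; under each permutation (subject-map sign flips for
#' one-sample tests, group-label permutations otherwise; the identity is
#' always included) the maximum enhanced statistic over the mask is
#' recorded, and fwe_p(v) is the fraction of permutations whose maximum
#' reaches the observed enhanced value at v. Hence fwe_p lies in
#' [1/P, 1] and is monotone decreasing in the observed TFCE value.
#'
#' @param M subjects x vertices matrix of change maps.
#' @param mesh `surface_mesh` carrying connectivity and vertex areas.
#' @param groups group labels (NULL for one-sample tests).
#' @param test "one_sample", "two_sample", or "anova".
#' @param tail for t tests: "left" (atrophy: mean < 0), "right", or "two";
#'   F tests are inherently one-sided.
#' @param tfce a `tfce_params`.
#' @param scheme a `permutation_scheme`; its kind must match the test.
#' @param mask cortex mask.
#' @param edges,areas optional precomputed connectivity/extent weights.
#' @return a `stat_report`: list with `stat_map`, `tfce_map`, `fwe_p`
#'   (metric maps), `max_dist` (permutation maxima), `n_perm`, `test`,
#'   `tail`.
#' @export
permutation_fwe <- function(M, mesh, groups = NULL,
                            test = c("one_sample", "two_sample", "anova"),
                            tail = c("left", "two", "right"),
                            tfce = tfce_params(),
                            scheme = permutation_scheme(),
                            mask = NULL, edges = NULL, areas = NULL) {
  test <- match.arg(test)
  tail <- match.arg(tail)
  if (is.null(edges)) edges <- mesh_edge_list(mesh)
  if (is.null(areas)) areas <- as.numeric(vertex_areas(mesh))
  mask <- as_mask(mask, ncol(M))
  M <- as.matrix(M)
  M[, !mask] <- 0
  M[is.na(M)] <- 0
  n <- nrow(M)

  orient <- function(t) switch(tail, left = -t, right = t, two = t)
  enhance <- function(stat, two_sided) {
    s <- stat
    if (!two_sided) s <- pmax(s, 0)
    as.numeric(tfce_enhance(s, mesh, tfce, mask, edges, areas))
  }

  if (test == "one_sample") {
    if (scheme$kind != "sign_flip")
      stop("one-sample tests need a sign_flip scheme")
    S <- sign_flip_matrix(n, scheme)
    P <- nrow(S)
    ssq <- colSums(M^2)
    means <- (S %*% M) / n
    vr <- sweep(-n * means^2, 2, ssq, `+`) / (n - 1)
    vr[vr < 1e-24] <- Inf
    T_all <- orient(means / sqrt(vr / n))
    two_sided <- tail == "two"
    obs_stat <- T_all[1, ]
  } else {
    if (is.null(groups)) stop("group tests need groups")
    if (scheme$kind != "label_permutation")
      stop("group tests need a label_permutation scheme")
    groups <- as.factor(groups)
    Pm <- label_perm_matrix(groups, scheme)
    P <- nrow(Pm)
    g <- nlevels(groups)
    m <- colMeans(M)
    sst <- colSums(M^2) - n * m^2
    T_all <- matrix(0, P, ncol(M))
    ng <- as.numeric(table(as.integer(groups)))
    for (i in seq_len(P)) {
      lab <- Pm[i, ]
      gs <- rowsum(M, lab)
      gm <- gs / ng
      if (test == "anova") {
        ssb <- colSums(ng * (gm - rep(m, each = g))^2)
        ssw <- pmax(sst - ssb, 1e-24)
        T_all[i, ] <- (ssb / (g - 1)) / (ssw / (n - g))
      } else {
        if (g != 2) stop("two_sample test needs exactly 2 groups")
        ssb <- colSums(ng * (gm - rep(m, each = g))^2)
        ssw <- pmax(sst - ssb, 1e-24)
        sp2 <- ssw / (n - 2)
        T_all[i, ] <- orient((gm[1, ] - gm[2, ]) /
                             sqrt(sp2 * (1 / ng[1] + 1 / ng[2])))
      }
    }
    two_sided <- if (test == "anova") FALSE else tail == "two"
    if (test == "anova") two_sided <- FALSE
    obs_stat <- T_all[1, ]
  }

  obs_tfce <- enhance(obs_stat, two_sided)
  max_dist <- numeric(P)
  max_dist[1] <- max(abs(obs_tfce))
  for (i in 2:P)
    max_dist[i] <- max(abs(enhance(T_all[i, ], two_sided)))
  cnt <- vapply(abs(obs_tfce), function(v) sum(max_dist >= v), numeric(1))
  fwe <- pmin(cnt / P, 1)
  fwe[!mask] <- 1
  fwe[fwe <= 0] <- 1 / P
  structure(list(stat_map = metric_map(obs_stat, mesh$name, "statistic"),
                 tfce_map = metric_map(obs_tfce, mesh$name, "statistic"),
                 fwe_p = metric_map(fwe, mesh$name, "p"),
                 max_dist = max_dist, n_perm = P, test = test, tail = tail),
            class = "stat_report")
}

#' Cohen's d
#'
#' Standardized mean difference (m1 - m2) / pooled SD.
#'
#' @param x,y numeric samples.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
             (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Global ANOVA with Tukey HSD pairwise comparisons and effect sizes
#'
#' One-way ANOVA of a global loss measure across diagnostic groups,
#' Tukey's Honest Significant Difference for all pairwise comparisons, and
#' Cohen's d per pair.
#'
#' @param values numeric vector of the measure (e.g. pct_volume_loss).
#' @param groups group labels.
#' @return list: `anova` (data.frame F, df, p), `pairwise` (data.frame
#'   pair, diff, p_adj, d).
#' @export
global_anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  sm <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$g
  pairs <- rownames(tuk)
  dvals <- vapply(pairs, function(p) {
    ab <- strsplit(p, "-", fixed = TRUE)[[1]]
    cohens_d(values[groups == ab[1]], values[groups == ab[2]])
  }, numeric(1))
  list(anova = data.frame(F = sm$`F value`[1], df1 = sm$Df[1],
                          df2 = sm$Df[2], p = sm$`Pr(>F)`[1]),
       pairwise = data.frame(pair = pairs, diff = tuk[, "diff"],
                             p_adj = tuk[, "p adj"], d = dvals,
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' ROI-level group tests: MANOVA and Bonferroni-corrected pairwise
#'
#' One-way MANOVA (Pillai's trace with its F approximation) of the per-ROI
#' change measures across groups, plus per-ROI pairwise two-sample t tests
#' with Bonferroni correction (factor = number of ROIs x number of group
#' pairs, capped at 1). If there are too few subjects for the full ROI set
#' the ROIs with largest variance are retained with a warning.
#'
#' @param roi_table data.frame from [roi_change_table()].
#' @param metric which change column to analyze ("d_thick_log2",
#'   "d_area_log2" or "d_vol_log2").
#' @return list: `manova` (data.frame pillai, F, df1, df2, p), `pairwise`
#'   (data.frame roi, pair, diff, p_raw, p_bonf), `rois_used`.
#' @export
roi_group_tests <- function(roi_table,
                            metric = c("d_vol_log2", "d_thick_log2",
                                       "d_area_log2")) {
  metric <- match.arg(metric)
  wide <- stats::reshape(
    roi_table[, c("subject_id", "group", "roi", metric)],
    idvar = c("subject_id", "group"), timevar = "roi",
    direction = "wide")
  groups <- as.factor(wide$group)
  Y <- as.matrix(wide[, -(1:2), drop = FALSE])
  colnames(Y) <- sub(paste0(metric, "."), "roi", colnames(Y), fixed = TRUE)
  n <- nrow(Y)
  g <- nlevels(groups)
  if (n < ncol(Y) + g) {
    keep <- order(apply(Y, 2, stats::var), decreasing = TRUE)
    keep <- sort(keep[seq_len(max(1, n - g - 1))])
    warning(sprintf("only %d subjects for %d ROIs: reduced to %d ROIs",
                    n, ncol(Y), length(keep)))
    Y <- Y[, keep, drop = FALSE]
  }
  sm <- NULL
  while (is.null(sm)) {
    fit <- stats::manova(Y ~ groups)
    sm <- tryCatch(summary(fit, test = "Pillai")$stats,
                   error = function(e) NULL)
    if (is.null(sm)) {
      if (ncol(Y) <= 1L) stop("singular ROI covariance; cannot test")
      keep <- order(apply(Y, 2, stats::var),
                    decreasing = TRUE)[seq_len(ncol(Y) %/% 2)]
      warning("singular within-covariance: reduced ROI set")
      Y <- Y[, sort(keep), drop = FALSE]
    }
  }
  man <- data.frame(pillai = sm[1, "Pillai"], F = sm[1, "approx F"],
                    df1 = sm[1, "num Df"], df2 = sm[1, "den Df"],
                    p = sm[1, "Pr(>F)"])
  lev <- levels(groups)
  prs <- utils::combn(lev, 2)
  n_tests <- ncol(Y) * ncol(prs)
  rows <- list()
  for (j in seq_len(ncol(Y))) {
    for (k in seq_len(ncol(prs))) {
      a <- Y[groups == prs[1, k], j]
      b <- Y[groups == prs[2, k], j]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = colnames(Y)[j], pair = paste(prs[1, k], prs[2, k], sep = "-"),
        diff = mean(a) - mean(b), p_raw = tt$p.value,
        p_bonf = min(1, tt$p.value * n_tests), stringsAsFactors = FALSE)
    }
  }
  list(manova = man, pairwise = do.call(rbind, rows),
       rois_used = colnames(Y))
}
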