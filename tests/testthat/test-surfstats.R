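test_that("one-sample t map matches the formula and flags degeneracy", {
  M <- rbind(c(-0.2, 1, 5), c(-0.1, 1, 5), c(-0.3, 1, 5))
  t <- one_sample_t_map(M)
  expect_equal(t[1], -0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(round(t[1], 4), -3.4641)
  expect_equal(t[2], 0) # zero variance flagged
  expect_true(2 %in% attr(t, "flagged"))
  expect_equal(as.numeric(one_sample_t_map(-M)), -as.numeric(t))

  # against t.test on random data
  set.seed(1)
  X <- matrix(rnorm(60), nrow = 10)
  tm <- one_sample_t_map(X)
  for (j in c(1, 4, 6))
    expect_equal(tm[j], unname(t.test(X[, j])$statistic), tolerance = 1e-9)
})

test_that("ANOVA F map matches aov sums of squares", {
  g <- rep(c("a", "b", "c"), each = 3)
  M0 <- matrix(rep(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 2), ncol = 2)
  f0 <- anova_f_map(M0, g)
  expect_equal(as.numeric(f0), c(0, 0), tolerance = 1e-9)

  expect_error(anova_f_map(matrix(0, 3, 2), c("a", "b", "c")), "n >= 2")
  deg <- anova_f_map(rbind(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_equal(deg[1], 0)
  expect_true(1 %in% attr(deg, "flagged"))

  set.seed(2)
  X <- matrix(rnorm(36), nrow = 9)
  fm <- anova_f_map(X, g)
  for (j in 1:2) {
    ref <- summary(aov(X[, j] ~ factor(g)))[[1]]$`F value`[1]
    expect_equal(fm[j], ref, tolerance = 1e-9)
  }
})

test_that("TFCE: null map, extent monotonicity, brute-force oracle", {
  m <- make_icosphere(2, 30)
  nv <- nrow(m$vertices)
  expect_equal(as.numeric(tfce_enhance(rep(0, nv), m)), rep(0, nv))

  # same-height blob beats an isolated vertex of equal height
  edges <- cortexshift:::mesh_edge_list(m)
  nbrs <- c(10, edges[edges[, 1] == 10, 2], edges[edges[, 2] == 10, 1])
  x <- numeric(nv)
  x[nbrs] <- 1
  x[100] <- 1
  e <- as.numeric(tfce_enhance(x, m))
  expect_gt(min(e[nbrs]), e[100])

  # dense-step brute force on a random field
  set.seed(3)
  v <- pmax(rnorm(nv), 0)
  areas <- as.numeric(vertex_areas(m))
  pars <- tfce_params(H = 2, E = 1, n_steps = 200)
  mine <- as.numeric(tfce_enhance(v, m, pars))
  ref <- tfce_bruteforce(v, m, areas, H = 2, E = 1, n_steps = 200)
  nz <- ref > 0
  expect_lt(max(abs(mine[nz] - ref[nz]) / ref[nz]), 1e-9)

  # scaling a positive map increases every nonzero value
  e1 <- as.numeric(tfce_enhance(v, m, pars))
  e2 <- as.numeric(tfce_enhance(2 * v, m, pars))
  expect_true(all(e2[e1 > 0] > e1[e1 > 0]))

  # a disjoint added cluster never decreases existing values
  v2 <- v
  far <- which(v == 0)[1:5]
  v2[far] <- max(v) / 2
  e3 <- as.numeric(tfce_enhance(v2, m, tfce_params(H = 2, E = 1, dh = 0.01)))
  e1d <- as.numeric(tfce_enhance(v, m, tfce_params(H = 2, E = 1, dh = 0.01)))
  expect_true(all(e3[e1d > 0] >= e1d[e1d > 0] - 1e-9))

  # negative lobes are enhanced symmetrically
  es <- as.numeric(tfce_enhance(-v, m, pars))
  expect_equal(es, -mine, tolerance = 1e-12)
})

test_that("permutation FWE: determinism, identity floor, strong signal", {
  m <- make_icosphere(2, 30)
  nv <- nrow(m$vertices)
  set.seed(7)
  n <- 12
  M <- matrix(rnorm(n * nv, 0, 0.1), n, nv)
  sig <- 1:20
  M[, sig] <- M[, sig] - 1 # strong atrophy signal
  sch <- permutation_scheme("sign_flip", 200, seed = 9)
  r1 <- permutation_fwe(M, m, test = "one_sample", tail = "left",
                        scheme = sch)
  r2 <- permutation_fwe(M, m, test = "one_sample", tail = "left",
                        scheme = sch)
  expect_identical(as.numeric(r1$fwe_p), as.numeric(r2$fwe_p))
  expect_equal(min(as.numeric(r1$fwe_p)), 1 / r1$n_perm)
  expect_true(all(as.numeric(r1$fwe_p)[sig] <= 0.05))
  expect_true(all(as.numeric(r1$fwe_p) >= 1 / r1$n_perm))

  # p monotone decreasing in the enhanced statistic
  o <- order(abs(as.numeric(r1$tfce_map)))
  expect_true(all(diff(as.numeric(r1$fwe_p)[o]) <= 1e-12))
})

test_that("exhaustive and sampled sign-flip p-values agree", {
  m <- make_icosphere(1, 30)
  nv <- nrow(m$vertices)
  set.seed(11)
  M <- matrix(rnorm(10 * nv, -0.3, 1), 10, nv)
  ex <- permutation_fwe(M, m, test = "one_sample", tail = "left",
                        scheme = permutation_scheme("sign_flip",
                                                    exhaustive = TRUE))
  expect_equal(ex$n_perm, 1024L)
  sm <- permutation_fwe(M, m, test = "one_sample", tail = "left",
                        scheme = permutation_scheme("sign_flip", 512,
                                                    seed = 2,
                                                    exhaustive = FALSE))
  expect_lt(max(abs(as.numeric(ex$fwe_p) - as.numeric(sm$fwe_p))), 0.05)
})

test_that("global ANOVA/Tukey/Cohen's d behave like the stats oracles", {
  set.seed(5)
  vals <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 2))
  g <- rep(c("CN", "MCI", "AD"), each = 6)
  res <- global_anova_tukey(vals, g)
  ref <- summary(aov(vals ~ factor(g)))[[1]]
  expect_equal(res$anova$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(res$anova$p, ref$`Pr(>F)`[1], tolerance = 1e-9)

  same <- global_anova_tukey(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$anova$F, 0, tolerance = 1e-12)
  expect_equal(same$pairwise$d, 0)

  # d: translation invariance and formula value
  expect_equal(cohens_d(c(0.5, 1.0, 1.5) + 7, c(1.5, 2.0, 2.5) + 7),
               cohens_d(c(0.5, 1.0, 1.5), c(1.5, 2.0, 2.5)))
  x <- c(0.5, 1.0, 1.5); y <- c(1.5, 2.0, 2.5) # means 1, 2; pooled sd 0.5
  expect_equal(cohens_d(y, x), 2.0, tolerance = 1e-12)
})

test_that("ROI MANOVA: Pillai oracle, Bonferroni arithmetic, reduction", {
  set.seed(6)
  n <- 8
  tab <- expand.grid(subject_id = sprintf("s%02d", 1:(2 * n)), roi = 1:2)
  tab$group <- rep(rep(c("A", "B"), each = n), 2)
  tab$d_vol_log2 <- rnorm(nrow(tab), sd = 0.05) +
    ifelse(tab$group == "B" & tab$roi == 1, -0.1, 0)
  res <- roi_group_tests(tab, "d_vol_log2")

  wide <- reshape(tab[, c("subject_id", "group", "roi", "d_vol_log2")],
                  idvar = c("subject_id", "group"), timevar = "roi",
                  direction = "wide")
  Y <- as.matrix(wide[, 3:4])
  expect_equal(res$manova$pillai, pillai_oracle(Y, wide$group),
               tolerance = 1e-10)
  expect_equal(res$pairwise$p_bonf,
               pmin(1, res$pairwise$p_raw * nrow(res$pairwise)))

  expect_equal(min(1, 0.01 * 20), 0.2) # Bonferroni is plain multiplication

  # too few subjects for the ROI count: reduced with a warning
  small <- expand.grid(subject_id = sprintf("t%d", 1:5), roi = 1:4)
  small$group <- rep(c("A", "A", "A", "B", "B"), 4)
  set.seed(9)
  small$d_vol_log2 <- rnorm(nrow(small))
  expect_warning(roi_group_tests(small, "d_vol_log2"), "reduced")
})
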