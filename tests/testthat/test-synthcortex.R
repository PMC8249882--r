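test_that("icosphere subdivision counts and Euler characteristic", {
  ico0 <- make_icosphere(0, 1)
  expect_equal(nrow(ico0$vertices), 12L)
  expect_equal(nrow(ico0$faces), 20L)

  ico3 <- make_icosphere(3, 1)
  expect_equal(nrow(ico3$vertices), 10 * 4^3 + 2)
  expect_equal(nrow(ico3$faces), 20 * 4^3)
  ne <- nrow(cortexshift:::mesh_edge_list(ico3))
  expect_equal(nrow(ico3$vertices) - ne + nrow(ico3$faces), 2L) # Euler

  expect_error(make_icosphere(8), "memory guard")
  # outward winding: positive triple products everywhere
  v <- ico3$vertices
  f <- ico3$faces
  d <- rowSums(v[f[, 1], ] * cortexshift:::cross3(v[f[, 2], ], v[f[, 3], ]))
  expect_true(all(d > 0))
})

test_that("pseudocortex: sphere limit, determinism, folding adds area", {
  s0 <- make_pseudocortex(2, 60, bumpiness = 0)
  expect_equal(sqrt(rowSums(s0$vertices^2)), rep(60, nrow(s0$vertices)),
               tolerance = 1e-12)

  a <- make_pseudocortex(4, 80, 0.2, seed = 13)
  b <- make_pseudocortex(4, 80, 0.2, seed = 13)
  expect_identical(a$vertices, b$vertices)

  expect_gt(total_area(a), 4 * pi * 80^2)
  expect_error(make_pseudocortex(2, 80, 0.99, seed = 1), "bumpiness")
})

test_that("atrophy deformation realizes its target fields", {
  base <- make_pseudocortex(3, 80, seed = 21)
  th <- rep(2.8, nrow(base$vertices))

  # zero spec, zero noise: identity
  z <- apply_atrophy(base, th, atrophy_spec(c(0, 0, 1), 50, 0, 0, 0, 0))
  expect_equal(z$mesh$vertices, base$vertices, tolerance = 1e-9)
  expect_equal(max(abs(z$truth$area)), 0, tolerance = 1e-9)
  expect_equal(max(abs(z$truth$volume)), 0, tolerance = 1e-9)

  # uniform areal scale: truth = global value everywhere (area ~ scale^2)
  u <- apply_atrophy(base, th, atrophy_spec(c(0, 0, 1), 50, 0, 0,
                                            global_log2_area = log2(0.9),
                                            global_log2_thickness = 0))
  expect_equal(as.numeric(u$truth$area),
               rep(log2(0.9), nrow(base$vertices)), tolerance = 1e-9)

  # localized patch: truth tracks the target inside, global level far away
  sp <- atrophy_spec(c(0, 0, 1), 50, -0.12, -0.10,
                     global_log2_area = -0.01, global_log2_thickness = 0)
  p <- apply_atrophy(base, th, sp)
  targ <- atrophy_targets(sp, base$sphere)
  theta <- acos(pmin(1, pmax(-1, base$sphere %*% c(0, 0, 1))))
  inside <- theta < sp$radius * 0.8
  far <- theta > sp$radius * 1.6
  expect_gt(cor(p$truth$area[inside], targ$area[inside]), 0.95)
  expect_lt(mean(abs(p$truth$area[inside] - targ$area[inside])), 0.015)
  expect_lt(max(abs(p$truth$area[far] - (-0.01))), 5e-3)
  expect_equal(p$truth$thickness, targ$thickness, tolerance = 1e-12)

  # ground-truth log2 additivity is exact by construction
  expect_identical(p$truth$volume, p$truth$area + p$truth$thickness)

  expect_error(apply_atrophy(base, th, atrophy_spec(c(0, 0, 1), 50, -1.5, 0)),
               "refused")
})

test_that("regridding: identity, rigid rotation, determinism", {
  m <- make_pseudocortex(4, 80, bumpiness = 0.04, seed = 4)
  set.seed(99)
  vals <- rnorm(nrow(m$vertices))
  id <- reparameterize(m, maps = list(v = vals), rotation = diag(3),
                       jitter_sd_deg = 0, seed = 1)
  expect_equal(id$mesh$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(id$maps$v, vals, tolerance = 1e-6)

  Rz <- cortexshift:::rotation_matrix(c(0, 0, 1), pi / 2)
  rot <- reparameterize(m, rotation = Rz, jitter_sd_deg = 0, seed = 1)
  expect_lt(abs(total_area(rot$mesh) - total_area(m)) / total_area(m),
            0.005)

  r1 <- reparameterize(m, rotation = 5, jitter_sd_deg = 0.1, seed = 42)
  r2 <- reparameterize(m, rotation = 5, jitter_sd_deg = 0.1, seed = 42)
  expect_identical(r1$mesh$vertices, r2$mesh$vertices)
})

test_that("cohort generation: determinism, bookkeeping, effect scaling", {
  z <- generate_cohort(2, c(A = 0, B = 0), noise_spec("none"), level = 2,
                       seed = 3, reparam = FALSE)
  expect_length(z, 4L)
  for (s in z) expect_equal(max(abs(s$truth$volume)), 0, tolerance = 1e-9)

  co <- generate_cohort(3, c(CN = 0, MCIS = 0.3, MCIC = 0.8, AD = 1),
                        level = 2, seed = 7, reparam = FALSE)
  expect_length(co, 12L)
  expect_equal(vapply(co, function(s) s$group, character(1)),
               rep(c("CN", "MCIS", "MCIC", "AD"), each = 3))
  co2 <- generate_cohort(3, c(CN = 0, MCIS = 0.3, MCIC = 0.8, AD = 1),
                         level = 2, seed = 7, reparam = FALSE)
  expect_identical(co[[5]]$followup$mesh$vertices,
                   co2[[5]]$followup$mesh$vertices)

  # mean effect magnitude scales with the group effect scale
  big <- generate_cohort(60, c(MCI = 0.5, AD = 1), noise_spec("none"),
                         level = 0, seed = 11, reparam = FALSE)
  eff <- vapply(big, function(s) s$effect, numeric(1))
  grp <- vapply(big, function(s) s$group, character(1))
  ratio <- mean(eff[grp == "AD"]) / mean(eff[grp == "MCI"])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("same subject re-generated under new noise keeps its atrophy truth", {
  a <- generate_subject("s", "G", 1, level = 2, seed = 31, noise_seed = 1,
                        noise = noise_spec("3T"), reparam = FALSE)
  b <- generate_subject("s", "G", 1, level = 2, seed = 31, noise_seed = 2,
                        noise = noise_spec("1.5T"), reparam = FALSE)
  expect_identical(a$truth$area, b$truth$area)
  expect_identical(a$effect, b$effect)
  expect_false(identical(a$followup$mesh$vertices, b$followup$mesh$vertices))
})
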