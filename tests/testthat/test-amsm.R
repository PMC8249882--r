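test_that("strain energy axioms: identity, rigid motion, scale, symmetry", {
  m <- random_bumpy_mesh(1, seed = 2)
  pars <- strain_params(1, 1, 1)

  expect_equal(strain_energy(m, m$vertices, pars)$total, 0,
               tolerance = 1e-12)

  R <- random_rotation(5)
  expect_equal(strain_energy(m, m$vertices %*% t(R) + 2, pars)$total, 0,
               tolerance = 1e-9)

  tri <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                      matrix(1:3, 1), validate = FALSE)
  s <- 1.2
  se <- strain_energy(tri, tri$vertices * s, pars)
  expect_equal(se$density, s^2 + 1 / s^2 - 2, tolerance = 1e-9)

  # J <-> 1/J symmetry for pure dilation
  up <- strain_energy(tri, tri$vertices * s, pars)$density
  dn <- strain_energy(tri, tri$vertices / s, pars)$density
  expect_equal(up, dn, tolerance = 1e-9)

  # non-negative on random deformations, zero only at isometry
  set.seed(8)
  def <- m$vertices + matrix(rnorm(length(m$vertices), sd = 0.05), ncol = 3)
  sd <- strain_energy(m, def, pars)
  expect_true(all(sd$density >= 0))
  expect_gt(sd$total, 0)

  # collapsed image triangle: large finite penalty, flagged
  col <- strain_energy(tri, matrix(1, 3, 3), pars)
  expect_true(col$flagged[1])
  expect_true(is.finite(col$total))
  expect_gt(col$total, 1e3)
})

test_that("matching feature: sphere guard, rigid invariance, amplitude scaling", {
  sph <- make_icosphere(2, 50)
  expect_warning(f0 <- compute_feature(sph), "weak feature")
  expect_equal(as.numeric(f0), rep(0, nrow(sph$vertices)))

  m <- make_pseudocortex(3, 80, 0.08, seed = 6)
  f <- compute_feature(m)
  R <- random_rotation(3)
  mr <- m
  mr$vertices <- sweep(m$vertices %*% t(R), 2, c(1, -2, 3), `+`)
  fr <- compute_feature(mr)
  expect_equal(as.numeric(fr), as.numeric(f), tolerance = 1e-9)

  m2 <- make_pseudocortex(3, 80, 0.16, seed = 6)
  r1 <- attr(compute_feature(m), "raw")
  r2 <- attr(compute_feature(m2), "raw")
  expect_equal(sd(r2) / sd(r1), 2, tolerance = 0.05)
})

test_that("area change from a correspondence matches direct recomputation", {
  m <- make_pseudocortex(3, 80, seed = 12)
  loc <- cortexshift:::precompute_locator(m$sphere, m$faces)
  hit <- cortexshift:::locate_on_sphere(loc, m$sphere)
  idcorr <- structure(list(warped = m$sphere, face = hit$face, w = hit$w),
                      class = "spherical_correspondence")
  ac <- area_change_from_correspondence(idcorr, m, m)
  expect_lt(max(abs(as.numeric(ac)), na.rm = TRUE), 1e-9)

  # uniform scale of the reference anatomy: area change = 2 log2(s)
  s <- 0.95
  ref <- m
  ref$vertices <- m$vertices * s
  ac2 <- area_change_from_correspondence(idcorr, m, ref)
  expect_lt(max(abs(as.numeric(ac2) - 2 * log2(s)), na.rm = TRUE), 0.01)

  # random smooth correspondence vs brute-force per-vertex recomputation
  set.seed(4)
  P <- m$sphere + 0.03 * matrix(rnorm(length(m$sphere)), ncol = 3)
  P <- P / sqrt(rowSums(P^2))
  hit2 <- cortexshift:::locate_on_sphere(loc, P)
  corr2 <- structure(list(warped = P, face = hit2$face, w = hit2$w),
                     class = "spherical_correspondence")
  ac3 <- as.numeric(area_change_from_correspondence(corr2, m, m,
                                                    subdivide = 0))
  X <- cortexshift:::interp_at(loc, hit2, m$vertices)
  img <- surface_mesh(X, m$faces, validate = FALSE)
  oracle <- log2(as.numeric(vertex_areas(img)) /
                 as.numeric(vertex_areas(m)))
  expect_equal(ac3, oracle, tolerance = 1e-10)
})

test_that("registration: self-identity, regularization limit, monotone objective", {
  m <- make_pseudocortex(3, 80, seed = 17)
  corr <- register_oneway(m, m, control_levels = 2)
  disp <- acos(pmin(1, rowSums(corr$warped * m$sphere)))
  expect_lt(mean(disp), 1e-3)

  m2 <- make_pseudocortex(3, 80, seed = 18) # different anatomy
  hard <- register_oneway(m, m2, strain_params(lambda_reg = 1e6),
                          mode = "spherical",
                          control_levels = 2, rigid_init = FALSE)
  disp2 <- acos(pmin(1, rowSums(hard$warped * m$sphere)))
  expect_lt(mean(disp2), 1e-2)

  soft <- register_oneway(m, m2, control_levels = 2:3)
  for (lv in soft$diagnostics)
    expect_true(all(diff(lv$objective) <= 1e-12))
})

test_that("registration recovers a known rotation", {
  m <- make_pseudocortex(3, 80, 0.08, seed = 19)
  ang <- 8 * pi / 180
  R <- cortexshift:::rotation_matrix(c(0.3, 1, 0.5), ang)
  ref <- m
  ref$vertices <- m$vertices %*% t(R)
  ref$sphere <- m$sphere %*% t(R)
  corr <- register_oneway(m, ref, control_levels = 2:3)
  target <- m$sphere %*% t(R)
  err <- acos(pmin(1, rowSums(corr$warped * target)))
  expect_lt(mean(err), 0.1 * ang)
})

test_that("bidirectional registration of identical timepoints is null", {
  m <- make_pseudocortex(3, 80, seed = 23)
  th <- rep(2.5, nrow(m$vertices))
  sub <- list(baseline = list(mesh = m, thickness = th),
              followup = list(mesh = m, thickness = th))
  reg <- register_bidirectional(sub, control_levels = 2)
  expect_false(reg$failed)
  expect_lt(max(abs(as.numeric(reg$area_change)), na.rm = TRUE), 1e-3)
})
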