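test_that("log2 change formula and masking", {
  expect_equal(as.numeric(log2_change(c(2, 2), c(2, 2))), c(0, 0))
  expect_equal(as.numeric(log2_change(2, 1)), -1)
  expect_equal(as.numeric(log2_change(3.0, 2.7)), log2(0.9),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(log2_change(3.0, 2.7)), 5), -0.15200)
  expect_warning(out <- log2_change(c(1, -1), c(1, 1)), "nonpositive")
  expect_true(is.na(out[2]))
  m <- log2_change(c(1, 2, 3), c(2, 2, 3), mask = c(TRUE, FALSE, TRUE))
  expect_true(is.na(m[2]))
})

test_that("change maps: null subject, additivity, thickness halving", {
  z <- tiny_subject(level = 3, effect_scale = 0, noise = "none")
  mz <- compute_change_maps(z, NULL, smoothing_params(20))
  msk <- mz$mask
  expect_lt(max(abs(as.numeric(mz$volume_change)[msk])), 1e-3)

  s <- tiny_subject(level = 3, effect_scale = 1, noise = "3T")
  mp <- compute_change_maps(s, NULL, smoothing_params(20))
  msk <- mp$mask
  lhs <- as.numeric(mp$volume_change)[msk]
  rhs <- as.numeric(mp$thickness_change_smoothed)[msk] +
    as.numeric(mp$area_change)[msk]
  expect_identical(lhs, rhs) # exact log2 additivity

  # thickness halved uniformly, area unchanged
  h <- z
  h$followup$thickness <- z$followup$thickness / 2
  mh <- compute_change_maps(h, NULL, smoothing_params(20))
  expect_equal(as.numeric(mh$thickness_change_smoothed)[mh$mask],
               rep(-1, sum(mh$mask)), tolerance = 1e-6)
  expect_lt(max(abs(as.numeric(mh$volume_change)[mh$mask] + 1)), 1e-3)
})

test_that("global summary: identities and the percent-loss relation", {
  z <- tiny_subject(level = 3, effect_scale = 0, noise = "none")
  g0 <- global_summary(z)
  expect_equal(g0$pct_thickness_loss, 0, tolerance = 1e-9)
  expect_equal(g0$pct_area_loss, 0, tolerance = 1e-9)

  s <- tiny_subject(level = 3, effect_scale = 1.5, noise = "3T")
  g <- global_summary(s)
  # (1 - v) = (1 - t)(1 - a) holds exactly since volume = mean x total
  expect_equal(1 - g$pct_volume_loss / 100,
               (1 - g$pct_thickness_loss / 100) *
                 (1 - g$pct_area_loss / 100), tolerance = 1e-12)
  expect_equal(g$volume_bl, g$thickness_bl * g$area_bl, tolerance = 1e-9)
  # worked numbers: area 1e5 -> 9.8e4, thickness 2.5 -> 2.45
  expect_equal((1 - 0.98 * 0.98) * 100, 3.96)
})

test_that("intrasubject variance uses the population convention", {
  fake <- list(thickness_change_smoothed = c(-1, 1),
               area_change = c(0.5, 0.5), volume_change = c(-0.5, 1.5),
               mask = c(TRUE, TRUE))
  v <- intrasubject_variance(fake)
  expect_equal(unname(v["thickness"]), 1)
  expect_equal(unname(v["area"]), 0)
  expect_equal(unname(v["volume"]), 1)
})

test_that("ROI change table: zero subject, localized atrophy, partition", {
  z <- tiny_subject(level = 3, effect_scale = 0, noise = "none")
  mz <- compute_change_maps(z, NULL, smoothing_params(20))
  tab <- roi_change_table(list(z), list(mz))
  expect_equal(nrow(tab), 19L) # 20 parcels minus the medial wall
  expect_lt(max(abs(tab$d_vol_log2)), 1e-6)
  expect_equal(tab$d_vol_log2, tab$d_thick_log2 + tab$d_area_log2,
               tolerance = 1e-12)

  # ROI baseline areas partition the global cortex area
  va <- as.numeric(vertex_areas(z$baseline$mesh))
  parc <- z$parcellation
  roi_area <- vapply(setdiff(1:20, z$wall_roi), function(r)
    sum(va[parc$labels == r & z$cortex]), numeric(1))
  expect_equal(sum(roi_area), total_area(z$baseline$mesh, z$cortex),
               tolerance = 1e-9)

  # atrophy confined to a small patch: change concentrates in its ROIs
  parc_dirs <- z$baseline$mesh$sphere
  roi_cen <- colMeans(parc_dirs[parc$labels == 5, ])
  roi_cen <- roi_cen / sqrt(sum(roi_cen^2))
  sp <- atrophy_spec(roi_cen, 14, -0.2, -0.2, 0, 0)
  s <- generate_subject("loc", "G", 1, spec = sp, level = 3,
                        noise = noise_spec("none"), reparam = FALSE,
                        seed = 5)
  ms <- compute_change_maps(s, NULL, smoothing_params(20))
  tb <- roi_change_table(list(s), list(ms))
  hit_roi <- tb$roi[which.max(abs(tb$d_area_log2))]
  theta_cen <- vapply(tb$roi, function(r) {
    d <- colMeans(parc_dirs[parc$labels == r, ])
    acos(min(1, sum(d / sqrt(sum(d^2)) * roi_cen)))
  }, numeric(1))
  expect_lt(theta_cen[tb$roi == hit_roi], 30 * pi / 180)
  quiet <- abs(theta_cen) > 60 * pi / 180
  expect_lt(max(abs(tb$d_area_log2[quiet])), 0.01)
})
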