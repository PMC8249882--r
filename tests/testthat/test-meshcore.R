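test_that("face areas match closed forms and Heron's formula", {
  eq <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                     matrix(1:3, 1), validate = FALSE)
  expect_equal(face_areas(eq), sqrt(3), tolerance = 1e-12)

  m <- random_bumpy_mesh(level = 0, seed = 3) # 20 faces
  expect_equal(face_areas(m), heron_face_areas(m), tolerance = 1e-12)

  R <- random_rotation(7)
  mr <- m
  mr$vertices <- m$vertices %*% t(R) + 10
  expect_equal(face_areas(mr), face_areas(m), tolerance = 1e-9)
})

test_that("vertex areas follow the 1/3-triangle rule and conserve area", {
  # regular octahedron with edge sqrt(2)
  oct <- surface_mesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                      rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                            c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6)))
  expect_equal(as.numeric(vertex_areas(oct)), rep(2 * sqrt(3) / 3, 6),
               tolerance = 1e-12)

  tri <- surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                      matrix(1:3, 1), validate = FALSE)
  expect_equal(as.numeric(vertex_areas(tri)), rep(6 / 3, 3))

  ico <- make_icosphere(3, 37)
  expect_lt(abs(sum(vertex_areas(ico)) - sum(face_areas(ico))) /
              sum(face_areas(ico)), 1e-12)
  for (s in 1:10) {
    m <- random_bumpy_mesh(level = sample(0:2, 1), seed = s)
    expect_lt(abs(sum(vertex_areas(m)) - sum(face_areas(m))) /
                sum(face_areas(m)), 1e-12)
  }
})

test_that("global summaries: means, totals, volume product, mask additivity", {
  m <- make_icosphere(3, 50)
  nv <- nrow(m$vertices)
  a_tot <- total_area(m)
  expect_equal(estimate_volume(m, rep(3, nv)), 3 * a_tot, tolerance = 1e-12)

  set.seed(1)
  th <- runif(nv, 1, 4)
  mask <- rep(TRUE, nv); mask[1:100] <- FALSE
  expect_equal(mean_thickness(th, mask), sum(th[mask]) / sum(mask))
  va <- as.numeric(vertex_areas(m))
  expect_equal(total_area(m) - total_area(m, mask), sum(va[!mask]),
               tolerance = 1e-9)
  expect_error(mean_thickness(th, rep(FALSE, nv)), "empty mask")
})

test_that("geodesic distances agree with a Dijkstra oracle", {
  g <- planar_grid_mesh(7, spacing = 2)
  d <- geodesic_distances(g, source = 1, radius = Inf)
  expect_equal(unname(d["2"]), 2) # direct neighbor: edge length
  ref <- dijkstra_oracle(g, 1)
  expect_equal(unname(d[as.character(seq_along(ref))]), ref,
               tolerance = 1e-12)
  d0 <- geodesic_distances(g, source = 5, radius = 0)
  expect_identical(names(d0), "5")
})

test_that("geodesic Gaussian smoothing: constants, delta oracle, limits", {
  g <- planar_grid_mesh(11, spacing = 1)
  nv <- nrow(g$vertices)
  sp <- smoothing_params(fwhm = 4)

  expect_equal(smooth_metric(rep(2.5, nv), g, sp), rep(2.5, nv),
               tolerance = 1e-12)

  # delta at the center vertex against a brute-force kernel oracle
  center <- 61
  delta <- numeric(nv); delta[center] <- 1
  sm <- smooth_metric(delta, g, sp)
  W <- matrix(0, nv, nv)
  for (s in seq_len(nv)) {
    dd <- dijkstra_oracle(g, s)
    k <- exp(-dd^2 / (2 * sp$sigma^2))
    k[dd > sp$truncation_radius * sp$sigma] <- 0
    W[s, ] <- k / sum(k)
  }
  expect_equal(sm, as.numeric(W %*% delta), tolerance = 1e-6)

  # near-delta kernel returns the input (with a warning)
  expect_warning(out <- smooth_metric(delta, g, smoothing_params(0.05)),
                 "near a delta")
  expect_equal(out, delta, tolerance = 1e-12)
})

test_that("smoothing is monotone and rigid-motion invariant", {
  m <- random_bumpy_mesh(2, seed = 9)
  nv <- nrow(m$vertices)
  sp <- smoothing_params(0.5)
  set.seed(2)
  x <- rnorm(nv)
  y <- x + runif(nv, 0, 1) # pointwise larger
  sx <- smooth_metric(x, m, sp)
  sy <- smooth_metric(y, m, sp)
  expect_true(all(sy >= sx - 1e-12))
  expect_gte(min(sx) + 1e-12, min(x))
  expect_lte(max(sx) - 1e-12, max(x))

  R <- random_rotation(4)
  mr <- m
  mr$vertices <- m$vertices %*% t(R) + 3
  expect_equal(smooth_metric(x, mr, sp), sx, tolerance = 1e-9)
})

test_that("icosahedron-face parcellation labels every vertex contiguously", {
  ico0 <- make_icosphere(0, 1)
  p0 <- build_parcellation(ico0)
  expect_length(p0$labels, 12L) # every icosahedron vertex is labeled
  expect_false(anyNA(p0$labels))
  expect_length(p0$roi_names, 20L)

  m <- make_icosphere(3, 1)
  p <- build_parcellation(m)
  expect_false(anyNA(p$labels))
  expect_setequal(unique(p$labels), 1:20)
  # contiguity by flood fill within each ROI
  edges <- cortexshift:::mesh_edge_list(m)
  for (r in 1:20) {
    vs <- which(p$labels == r)
    keep <- edges[edges[, 1] %in% vs & edges[, 2] %in% vs, , drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(match(keep, vs), ncol = 2),
                                     directed = FALSE)
    if (igraph::vcount(g) < length(vs))
      g <- igraph::add_vertices(g, length(vs) - igraph::vcount(g))
    expect_equal(igraph::components(g)$no, 1)
  }

  wall <- medial_wall_mask(p, wall_roi = 7)
  ctx <- cortex_mask(p, wall_roi = 7)
  expect_equal(sum(ctx), nrow(m$vertices) - sum(wall))
  expect_false(any(wall & ctx))

  bad <- surface_mesh(m$vertices, m$faces, validate = FALSE)
  expect_error(build_parcellation(bad), "subdivision")
})
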