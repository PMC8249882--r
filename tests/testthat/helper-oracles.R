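# Independent oracles and fixture builders used across the tests.

# Heron's formula per face, independent of the cross-product route.
heron_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- sqrt(rowSums((v[f[, 2], ] - v[f[, 1], ])^2))
  b <- sqrt(rowSums((v[f[, 3], ] - v[f[, 2], ])^2))
  c <- sqrt(rowSums((v[f[, 1], ] - v[f[, 3], ])^2))
  s <- (a + b + c) / 2
  sqrt(pmax(s * (s - a) * (s - b) * (s - c), 0))
}

# Plain O(V^2) Dijkstra on the mesh edge graph.
dijkstra_oracle <- function(mesh, source) {
  v <- mesh$vertices
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  n <- nrow(v)
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb1 <- e[e[, 1] == u, 2]; wb1 <- w[e[, 1] == u]
    nb2 <- e[e[, 2] == u, 1]; wb2 <- w[e[, 2] == u]
    nb <- c(nb1, nb2); wb <- c(wb1, wb2)
    relax <- dist[u] + wb < dist[nb]
    dist[nb[relax]] <- dist[u] + wb[relax]
  }
  dist
}

# Triangulated planar n x n grid with given spacing.
planar_grid_mesh <- function(n = 9, spacing = 1) {
  xy <- expand.grid(x = seq_len(n), y = seq_len(n)) * spacing
  v <- cbind(xy$x, xy$y, 0)
  idx <- function(i, j) (j - 1) * n + i
  f <- list()
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      f[[length(f) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  surface_mesh(v, do.call(rbind, f), name = "grid")
}

# Random valid closed mesh: icosphere radially perturbed per vertex.
random_bumpy_mesh <- function(level = 1, seed = 1) {
  set.seed(seed)
  m <- make_icosphere(level, radius = 1)
  r <- 1 + runif(nrow(m$vertices), -0.3, 0.3)
  m$vertices <- m$vertices * r
  m
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3)
  cortexshift:::rotation_matrix(ax, runif(1, 0.3, 2))
}

# Brute-force TFCE: explicit loop over thresholds with connected components
# found by igraph on the suprathreshold subgraph.
tfce_bruteforce <- function(values, mesh, areas, H, E, n_steps) {
  edges <- cortexshift:::mesh_edge_list(mesh)
  mx <- max(values)
  out <- numeric(length(values))
  if (mx <= 0) return(out)
  dh <- mx / n_steps
  for (h in seq(dh, mx + 1e-12, by = dh)) {
    supra <- which(values >= h)
    if (!length(supra)) break
    keep <- edges[edges[, 1] %in% supra & edges[, 2] %in% supra, ,
                  drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(match(keep, supra),
                                            ncol = 2), directed = FALSE)
    ng <- igraph::vcount(g)
    if (ng < length(supra))
      g <- igraph::add_vertices(g, length(supra) - ng)
    comp <- igraph::components(g)$membership
    ext <- tapply(areas[supra], comp, sum)
    out[supra] <- out[supra] + as.numeric(ext[comp])^E * h^H * dh
  }
  out
}

# Pillai's trace from first principles: eigenvalues of solve(W+B) %*% B.
pillai_oracle <- function(Y, groups) {
  groups <- as.factor(groups)
  gm <- rowsum(Y, groups) / as.numeric(table(groups))
  m <- colMeans(Y)
  B <- matrix(0, ncol(Y), ncol(Y))
  for (g in levels(groups)) {
    d <- gm[g, ] - m
    B <- B + sum(groups == g) * outer(d, d)
  }
  W <- matrix(0, ncol(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) {
    d <- Y[i, ] - gm[as.character(groups[i]), ]
    W <- W + outer(d, d)
  }
  sum(diag(solve(W + B) %*% B))
}

# Small registration-free subject: two timepoints on a shared grid.
tiny_subject <- function(level = 2, effect_scale = 1, noise = "none",
                         seed = 5) {
  generate_subject("tiny", "G", effect_scale, level = level,
                   noise = noise_spec(noise), reparam = FALSE, seed = seed)
}
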