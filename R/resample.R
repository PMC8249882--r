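# Spherical point location and barycentric resampling.
#
# Queries are located on a spherical triangulation by nearest-vertex search
# (blocked dot-product argmax) followed by a gnomonic barycentric test of
# the faces incident to the nearest vertex; the rare query falling outside
# all of them (possible on strongly warped grids) is resolved by an
# exhaustive face scan. Barycentric weights are >= 0 and sum to 1.

precompute_locator <- function(sphere, faces) {
  nv <- nrow(sphere)
  nf <- nrow(faces)
  # inverse of [v1 v2 v3] (columns) per face, stored as 9 columns (row-major)
  Minv <- matrix(0, nf, 9)
  a <- sphere[faces[, 1], , drop = FALSE]
  b <- sphere[faces[, 2], , drop = FALSE]
  c <- sphere[faces[, 3], , drop = FALSE]
  # adjugate / det for the 3x3 with columns a,b,c
  cx <- function(p, q) cross3(p, q)
  det <- rowSums(a * cx(b, c))
  r1 <- cx(b, c) / det
  r2 <- cx(c, a) / det
  r3 <- cx(a, b) / det
  Minv <- cbind(r1, r2, r3) # rows of M^-1 stacked: w_i = r_i . q
  # incident faces per vertex (padded with 0)
  idx <- as.vector(faces)
  fid <- rep(seq_len(nf), 3L)
  o <- order(idx)
  idx <- idx[o]; fid <- fid[o]
  counts <- tabulate(idx, nbins = nv)
  maxdeg <- max(counts)
  inc <- matrix(0L, nv, maxdeg)
  pos <- c(0, cumsum(counts))
  for (k in seq_len(maxdeg)) {
    has <- which(counts >= k)
    inc[has, k] <- fid[pos[has] + k]
  }
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  list(sphere = sphere, faces = faces, Minv = Minv, inc = inc,
       maxdeg = maxdeg, edges = e)
}

nearest_vertex <- function(sphere, Q, edges = NULL, block = 2048L) {
  if (!is.null(edges))
    return(nearest_vertex_cpp(sphere, edges, Q, integer(0)))
  m <- nrow(Q)
  out <- integer(m)
  for (start in seq(1L, m, by = block)) {
    rows <- start:min(start + block - 1L, m)
    d <- Q[rows, , drop = FALSE] %*% t(sphere)
    out[rows] <- max.col(d, ties.method = "first")
  }
  out
}

bary_weights_for_faces <- function(loc, face_ids, Q) {
  # raw (unnormalized) gnomonic barycentric weights of each query in the
  # given face; rows with face_id 0 get -Inf score
  M <- loc$Minv[pmax(face_ids, 1L), , drop = FALSE]
  w1 <- M[, 1] * Q[, 1] + M[, 2] * Q[, 2] + M[, 3] * Q[, 3]
  w2 <- M[, 4] * Q[, 1] + M[, 5] * Q[, 2] + M[, 6] * Q[, 3]
  w3 <- M[, 7] * Q[, 1] + M[, 8] * Q[, 2] + M[, 9] * Q[, 3]
  s <- w1 + w2 + w3
  bad <- face_ids == 0L | s <= 0
  w <- cbind(w1, w2, w3) / s
  w[bad, ] <- -Inf
  w
}

locate_on_sphere <- function(loc, Q) {
  Q <- Q / sqrt(rowSums(Q^2))
  m <- nrow(Q)
  nn <- nearest_vertex(loc$sphere, Q, loc$edges)
  best_face <- integer(m)
  best_score <- rep(-Inf, m)
  best_w <- matrix(0, m, 3)
  for (k in seq_len(loc$maxdeg)) {
    fk <- loc$inc[nn, k]
    w <- bary_weights_for_faces(loc, fk, Q)
    score <- pmin(w[, 1], pmin(w[, 2], w[, 3]))
    better <- score > best_score
    if (any(better)) {
      best_score[better] <- score[better]
      best_face[better] <- fk[better]
      best_w[better, ] <- w[better, , drop = FALSE]
    }
  }
  # fallback: queries outside the one-ring of their nearest vertex
  bad <- which(best_score < -1e-6)
  for (q in bad) {
    wall <- bary_weights_for_faces(loc, seq_len(nrow(loc$faces)),
                                   matrix(Q[q, ], nrow(loc$faces), 3,
                                          byrow = TRUE))
    sc <- pmin(wall[, 1], pmin(wall[, 2], wall[, 3]))
    j <- which.max(sc)
    best_face[q] <- j
    best_w[q, ] <- wall[j, ]
    best_score[q] <- sc[j]
  }
  best_w <- pmax(best_w, 0)
  best_w <- best_w / rowSums(best_w)
  list(face = best_face, w = best_w)
}

interp_at <- function(loc, hit, values) {
  f <- loc$faces[hit$face, , drop = FALSE]
  if (is.matrix(values)) {
    hit$w[, 1] * values[f[, 1], , drop = FALSE] +
      hit$w[, 2] * values[f[, 2], , drop = FALSE] +
      hit$w[, 3] * values[f[, 3], , drop = FALSE]
  } else {
    hit$w[, 1] * values[f[, 1]] + hit$w[, 2] * values[f[, 2]] +
      hit$w[, 3] * values[f[, 3]]
  }
}

sample_directions <- function(d, rotation, jitter_sd_deg, seed) {
  with_seed(seed, {
    R <- if (is.matrix(rotation)) rotation else
      rotation_matrix(stats::rnorm(3), rotation * pi / 180)
    out <- d %*% t(R)
    if (jitter_sd_deg > 0) {
      jit <- matrix(stats::rnorm(length(d), sd = jitter_sd_deg * pi / 180),
                    ncol = 3)
      jit <- jit - rowSums(jit * out) * out
      out <- out + jit
      out <- out / sqrt(rowSums(out^2))
    }
  })
  out
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Resample a surface onto a rotated/jittered spherical grid
#'
#' Emulates the fact that two real scans share no vertex grid: the surface
#' (and any attached per-vertex maps) is resampled by barycentric
#' interpolation at a standard icosphere grid whose sampling directions are
#' rotated by `rotation` (a 3x3 matrix, or an angle in degrees about a
#' random axis) and perturbed per-vertex by tangential jitter. The returned
#' mesh's own parameterization is the standard (unrotated) icosphere, so
#' the correspondence to the original grid now includes the rotation.
#'
#' @param mesh `surface_mesh` with icosphere-grid sphere parameterization.
#' @param maps named list of per-vertex maps to transfer (vectors).
#' @param rotation 3x3 rotation matrix, or rotation angle in degrees.
#' @param jitter_sd_deg per-vertex tangential jitter SD (degrees).
#' @param seed integer seed (random axis and jitter).
#' @return list: `mesh` (resampled), `maps` (transferred maps).
#' @export
reparameterize <- function(mesh, maps = list(), rotation = 5,
                           jitter_sd_deg = 0.3, seed = 1L) {
  if (is.null(mesh$sphere)) stop("mesh must carry a sphere")
  if (is.null(mesh$ico)) stop("mesh must be an icosphere-grid surface")
  grid <- make_icosphere(mesh$ico$level, 1)
  d <- grid$sphere
  sample_dirs <- sample_directions(d, rotation, jitter_sd_deg, seed)
  loc <- precompute_locator(mesh$sphere, mesh$faces)
  hit <- locate_on_sphere(loc, sample_dirs)
  v <- interp_at(loc, hit, mesh$vertices)
  out <- surface_mesh(v, grid$faces, name = paste0(mesh$name, ".regrid"),
                      sphere = d, validate = FALSE)
  fa <- face_areas(out)
  if (any(fa <= 0)) stop("jitter collapsed triangles during resampling")
  out$ico <- grid$ico
  out$radial <- mesh$radial
  new_maps <- lapply(maps, function(m) interp_at(loc, hit, as.numeric(m)))
  list(mesh = out, maps = new_maps)
}
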