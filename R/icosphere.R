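#' Icosphere meshes by recursive subdivision
#'
#' Builds a geodesic sphere by recursive 4-fold midpoint subdivision of the
#' regular icosahedron, projecting new vertices to the sphere. A level-L
#' icosphere has 10 * 4^L + 2 vertices and 20 * 4^L faces; level 5 gives the
#' 10,242-vertex grid used as the registration control/data resolution.
#' The subdivision ancestry (which of the 20 base faces each triangle
#' descends from) is retained for the toy parcellation.
#'
#' @param level subdivision level (0 = icosahedron). Levels above 7 are
#'   refused as a memory guard.
#' @param radius sphere radius in mm.
#' @return a `surface_mesh` whose `sphere` field holds the unit directions,
#'   with an `ico` element (list: `level`, `base_face` per face).
#' @export
make_icosphere <- function(level = 3L, radius = 1) {
  if (level < 0) stop("level must be >= 0")
  if (level > 7) stop("level > 7 refused (memory guard)")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  base_face <- seq_len(20L)
  if (level > 0) {
    for (l in seq_len(level)) {
      nv <- nrow(v)
      e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
      ekey <- as.numeric(pmin(e[, 1], e[, 2])) * (nv + 1) + pmax(e[, 1], e[, 2])
      ued <- !duplicated(ekey)
      mid_of <- match(ekey, ekey[ued])
      mids <- (v[e[ued, 1], , drop = FALSE] + v[e[ued, 2], , drop = FALSE]) / 2
      mids <- mids / sqrt(rowSums(mids^2))
      v <- rbind(v, mids)
      nf <- nrow(f)
      m12 <- nv + mid_of[seq_len(nf)]
      m23 <- nv + mid_of[nf + seq_len(nf)]
      m31 <- nv + mid_of[2 * nf + seq_len(nf)]
      f <- rbind(cbind(f[, 1], m12, m31),
                 cbind(m12, f[, 2], m23),
                 cbind(m31, m23, f[, 3]),
                 cbind(m12, m23, m31))
      base_face <- rep(base_face, 4L)
    }
  }
  # enforce outward winding (positive triple product with face centroid)
  c1 <- v[f[, 1], , drop = FALSE]
  c2 <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det <- rowSums(c1 * cross3(c2, c3))
  flip <- det < 0
  if (any(flip)) f[flip, ] <- f[flip, c(1, 3, 2)]
  m <- surface_mesh(v * radius, f, name = sprintf("icosphere%d", level),
                    sphere = v, validate = FALSE)
  m$ico <- list(level = as.integer(level), base_face = base_face)
  m
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Toy cortical parcellation from icosahedron ancestry
#'
#' Labels every vertex of a subdivision-structured icosphere by the base
#' icosahedron face its triangles descend from, giving 20 contiguous ROIs
#' that stand in structurally for a gyral atlas; vertices on ROI boundaries
#' are assigned to the lowest adjacent ROI id. One designated ROI plays the
#' medial wall.
#'
#' @param mesh a mesh built by [make_icosphere()] (or deformations of it
#'   that keep the `ico` ancestry).
#' @return a `parcellation`: list with `labels` (integer per vertex),
#'   `roi_names`.
#' @export
build_parcellation <- function(mesh) {
  if (is.null(mesh$ico)) stop("mesh is not subdivision-structured")
  nv <- n_vertices(mesh)
  lab <- rep.int(NA_integer_, nv)
  idx <- as.vector(mesh$faces)
  bf <- rep(mesh$ico$base_face, 3L)
  # per-vertex minimum adjacent base face
  o <- order(idx, bf)
  first <- !duplicated(idx[o])
  lab[idx[o][first]] <- bf[o][first]
  if (anyNA(lab)) stop("mesh has unlabeled (isolated) vertices")
  structure(list(labels = lab,
                 roi_names = sprintf("roi%02d", seq_len(20L))),
            class = "parcellation")
}

#' Medial wall and cortex masks from a parcellation
#'
#' @param parcellation a `parcellation`.
#' @param wall_roi integer id of the ROI designated as medial wall.
#' @return `medial_wall_mask`: a `vertex_mask` (role "medial_wall");
#'   `cortex_mask`: its complement (role "cortex").
#' @export
medial_wall_mask <- function(parcellation, wall_roi = 1L) {
  vertex_mask(parcellation$labels == wall_roi, "medial_wall")
}

#' @rdname medial_wall_mask
#' @export
cortex_mask <- function(parcellation, wall_roi = 1L) {
  vertex_mask(parcellation$labels != wall_roi, "cortex")
}
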