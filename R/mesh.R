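#' Triangulated cortical surface mesh
#'
#' Constructs a `surface_mesh`: a triangulated 2-manifold given by an
#' `n x 3` matrix of vertex coordinates (mm) and an `m x 3` integer matrix
#' of 1-based vertex indices. An optional `sphere` holds the spherical
#' parameterization of the surface: unit vectors, one per vertex, with the
#' same triangulation.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle (1-based indices).
#' @param name label for the mesh (e.g. "lh.baseline").
#' @param sphere optional numeric matrix of unit vectors (same rows as
#'   `vertices`) giving the spherical parameterization.
#' @param validate run manifoldness/degeneracy checks (disable for meshes
#'   already validated upstream).
#' @return an object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `name`, `sphere`.
#' @export
surface_mesh <- function(vertices, faces, name = "mesh", sphere = NULL,
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  nv <- nrow(vertices)
  if (validate) {
    if (any(faces < 1L) || any(faces > nv)) stop("face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("face with repeated vertex")
    e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (any(table(key) > 2L)) stop("edge shared by more than two faces")
  }
  if (!is.null(sphere)) {
    sphere <- as.matrix(sphere)
    if (!all(dim(sphere) == dim(vertices)))
      stop("sphere must match vertices in dimension")
    sphere <- sphere / sqrt(rowSums(sphere^2))
  }
  structure(list(vertices = vertices, faces = faces, name = name,
                 sphere = sphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d faces%s\n", x$name,
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$sphere)) "" else ", with sphere"))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-vertex metric map
#'
#' A scalar value per vertex of a named mesh. Stored as a plain numeric
#' vector with `units` and `mesh_name` attributes; all package functions
#' also accept bare numeric vectors of the right length.
#'
#' @param values numeric vector, one value per vertex.
#' @param mesh_name label of the mesh the map lives on.
#' @param units one of "mm", "mm2", "mm3", "log2-ratio", "statistic", "p",
#'   "zscore", "none".
#' @export
metric_map <- function(values, mesh_name = "mesh", units = "none") {
  units <- match.arg(units, c("mm", "mm2", "mm3", "log2-ratio", "statistic",
                              "p", "zscore", "none"))
  if (units == "p" && (any(values <= 0, na.rm = TRUE) ||
                       any(values > 1, na.rm = TRUE)))
    stop("p-value maps must lie in (0, 1]")
  structure(as.numeric(values), mesh_name = mesh_name, units = units,
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric_map on '%s' (%s): %d values, range [%.4g, %.4g]\n",
              attr(x, "mesh_name"), attr(x, "units"), length(x),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Per-vertex boolean mask
#'
#' @param flags logical vector, one per vertex.
#' @param role "cortex" or "medial_wall".
#' @export
vertex_mask <- function(flags, role = c("cortex", "medial_wall")) {
  role <- match.arg(role)
  structure(as.logical(flags), role = role, class = "vertex_mask")
}

as_mask <- function(mask, nv) {
  if (is.null(mask)) return(rep(TRUE, nv))
  mask <- as.logical(mask)
  if (length(mask) != nv) stop("mask length must equal vertex count")
  mask
}

#' Triangle areas of a surface mesh
#'
#' Area of each face as half the norm of the cross product of two edge
#' vectors. Degenerate (zero-area) faces get area 0 with a warning.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  a <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(a == 0)) warning("degenerate face(s) with zero area")
  a
}

#' Vertex-wise surface area
#'
#' Attributes one third of each triangle's area to each of its vertices, so
#' that the vertex areas sum exactly to the total mesh area.
#'
#' @param mesh a `surface_mesh`.
#' @return a `metric_map` of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  nv <- n_vertices(mesh)
  va <- numeric(nv)
  third <- rep(fa / 3, 3L)
  idx <- as.vector(mesh$faces)
  va <- unname(rowsum(third, idx, reorder = TRUE))
  out <- numeric(nv)
  out[sort(unique(idx))] <- va
  if (length(unique(idx)) < nv) warning("isolated vertex with zero area")
  metric_map(out, mesh$name, "mm2")
}

#' Global cortical summaries
#'
#' `total_area` sums per-vertex areas over the cortex mask; `mean_thickness`
#' averages thickness over masked vertices (unweighted by default, as the
#' global thickness measure); `estimate_volume` is their product.
#'
#' @param mesh a `surface_mesh`.
#' @param mask logical cortex mask (TRUE = include); NULL for all vertices.
#' @param thickness per-vertex thickness (mm).
#' @param area_weighted if TRUE, weight the thickness mean by vertex area.
#' @return scalar (mm^2, mm, mm^3 respectively).
#' @export
total_area <- function(mesh, mask = NULL) {
  mask <- as_mask(mask, n_vertices(mesh))
  if (!any(mask)) stop("empty mask")
  sum(vertex_areas(mesh)[mask])
}

#' @rdname total_area
#' @export
mean_thickness <- function(thickness, mask = NULL, mesh = NULL,
                           area_weighted = FALSE) {
  mask <- as_mask(mask, length(thickness))
  if (!any(mask)) stop("empty mask")
  if (area_weighted) {
    if (is.null(mesh)) stop("area_weighted mean needs the mesh")
    w <- as.numeric(vertex_areas(mesh))[mask]
    sum(thickness[mask] * w) / sum(w)
  } else {
    mean(thickness[mask])
  }
}

#' @rdname total_area
#' @export
estimate_volume <- function(mesh, thickness, mask = NULL,
                            area_weighted = FALSE) {
  mean_thickness(thickness, mask, mesh, area_weighted) * total_area(mesh, mask)
}

mesh_edge_list <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

mesh_graph <- function(mesh) {
  e <- mesh_edge_list(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < n_vertices(mesh))
    g <- igraph::add_vertices(g, n_vertices(mesh) - igraph::vcount(g))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distances along the mesh edge graph
#'
#' Shortest-path distance from a source vertex, with Euclidean edge lengths
#' as weights, restricted to vertices within `radius`. This is the graph
#' geodesic, not the exact polyhedral geodesic; it is adequate when used at
#' scales well above the mean edge length (as in kernel smoothing).
#'
#' @param mesh a `surface_mesh`.
#' @param source 1-based source vertex index.
#' @param radius maximum distance (mm); `Inf` for the whole mesh.
#' @return named numeric vector of distances for vertices within radius
#'   (names = vertex indices); unreachable vertices are omitted.
#' @export
geodesic_distances <- function(mesh, source, radius = Inf) {
  g <- mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = source, mode = "all"))
  names(d) <- seq_along(d)
  d[is.finite(d) & d <= radius]
}

#' Smoothing kernel parameters
#'
#' @param fwhm full width at half maximum of the Gaussian kernel (mm);
#'   sigma = fwhm / (2 sqrt(2 ln 2)).
#' @param truncation_radius kernel support radius in multiples of sigma.
#' @export
smoothing_params <- function(fwhm = 20, truncation_radius = 3) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (truncation_radius <= 0) stop("truncation_radius must be positive")
  structure(list(fwhm = fwhm, sigma = fwhm / (2 * sqrt(2 * log(2))),
                 truncation_radius = truncation_radius),
            class = "smoothing_params")
}

#' Geodesic Gaussian smoothing matrix
#'
#' Builds the sparse row-stochastic smoothing operator for a mesh: entry
#' (v, w) proportional to exp(-d(v,w)^2 / (2 sigma^2)) for geodesic distance
#' d below the truncation radius, normalized per target vertex over the
#' masked support. Row normalization preserves constant maps exactly.
#'
#' @param mesh a `surface_mesh`.
#' @param params a `smoothing_params`.
#' @param mask logical support mask (e.g. cortex); masked-out vertices
#'   neither contribute nor receive smoothed values.
#' @return sparse `Matrix::dgCMatrix`, rows sum to 1 on the mask.
#' @export
smoothing_matrix <- function(mesh, params, mask = NULL) {
  nv <- n_vertices(mesh)
  mask <- as_mask(mask, nv)
  cutoff <- params$truncation_radius * params$sigma
  el <- mesh_edge_list(mesh)
  ew <- sqrt(rowSums((mesh$vertices[el[, 1], , drop = FALSE] -
                      mesh$vertices[el[, 2], , drop = FALSE])^2))
  if (params$fwhm < mean(ew))
    warning("FWHM below mean edge length: kernel is near a delta")
  keep <- which(mask)
  balls <- geodesic_balls_cpp(nv, el, ew, keep, cutoff)
  ok <- mask[balls$j]
  S <- Matrix::sparseMatrix(i = balls$i[ok], j = balls$j[ok],
                            x = exp(-balls$d[ok]^2 / (2 * params$sigma^2)),
                            dims = c(nv, nv))
  rs <- Matrix::rowSums(S)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% S
}

#' Smooth a metric map on a surface
#'
#' Truncated geodesic-distance Gaussian smoothing with per-vertex weight
#' normalization over the masked support (conserves constants, satisfies the
#' max principle). The 20 mm FWHM default matches common practice for
#' cortical thickness maps.
#'
#' @param metric per-vertex values.
#' @param mesh a `surface_mesh`.
#' @param params a `smoothing_params`.
#' @param mask support mask; values outside it pass through unchanged.
#' @param S optional precomputed smoothing matrix (from
#'   [smoothing_matrix()]) to amortize over many maps.
#' @return smoothed values (same length, `metric_map` if input was one).
#' @export
smooth_metric <- function(metric, mesh, params = smoothing_params(),
                          mask = NULL, S = NULL) {
  nv <- n_vertices(mesh)
  if (length(metric) != nv) stop("metric length must equal vertex count")
  mask <- as_mask(mask, nv)
  if (is.null(S)) S <- smoothing_matrix(mesh, params, mask)
  out <- as.numeric(S %*% as.numeric(metric))
  out[!mask] <- metric[!mask]
  if (inherits(metric, "metric_map"))
    out <- metric_map(out, attr(metric, "mesh_name"), attr(metric, "units"))
  out
}
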