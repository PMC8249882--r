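#' Strain-energy parameters for registration
#'
#' Weights of the deformation penalty. For principal in-plane stretches
#' lambda1, lambda2 of a triangle, the energy density is
#' W = c_shear * (R/2 - 1) + c_bulk * (J + 1/J - 2) with J = lambda1*lambda2
#' (area change) and R = lambda1/lambda2 + lambda2/lambda1 (shape change):
#' non-negative, zero exactly at isometries, invariant under rigid motion,
#' and symmetric under J <-> 1/J for pure dilation.
#'
#' @param c_shear weight of the shape-change (shear) term.
#' @param c_bulk weight of the size-change (bulk) term.
#' @param lambda_reg overall weight of strain (per unit area) against the
#'   feature-similarity term in the registration objective.
#' @export
strain_params <- function(c_shear = 1, c_bulk = 1, lambda_reg = 1) {
  if (c_shear < 0 || c_bulk < 0 || lambda_reg < 0)
    stop("strain parameters must be >= 0")
  structure(list(c_shear = c_shear, c_bulk = c_bulk,
                 lambda_reg = lambda_reg), class = "strain_params")
}

# 2-D rest-state edge coordinates per face: e1 along x, e2 in upper half.
rest_frame <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  a <- sqrt(rowSums(e1^2))
  b <- rowSums(e1 * e2) / a
  c2 <- rowSums(e2^2) - b^2
  cc <- sqrt(pmax(c2, 0))
  area <- 0.5 * a * cc
  # inverse of rest matrix [[a, b], [0, cc]]
  list(inv11 = 1 / a, inv12 = -b / (a * cc), inv22 = 1 / cc, area = area)
}

strain_face_density <- function(rest, X1, X2, X3, params,
                                penalty = 1e6) {
  d1 <- X2 - X1
  d2 <- X3 - X1
  p <- sqrt(rowSums(d1^2))
  q <- rowSums(d1 * d2) / pmax(p, 1e-300)
  r2 <- rowSums(d2^2) - q^2
  r <- sqrt(pmax(r2, 0))
  # F = D %*% Rest^-1 with D = [[p, q], [0, r]]
  f11 <- p * rest$inv11
  f12 <- p * rest$inv12 + q * rest$inv22
  f22 <- r * rest$inv22
  I1 <- f11^2 + f12^2 + f22^2
  J <- f11 * f22
  bad <- !is.finite(J) | J < 1e-9
  Js <- ifelse(bad, 1, J)
  W <- params$c_shear * (I1 / (2 * Js) - 1) +
    params$c_bulk * (Js + 1 / Js - 2)
  W[bad] <- penalty
  list(W = W, flagged = bad)
}

#' Strain energy of a surface deformation
#'
#' For each baseline triangle and its deformed image (one 3-D point per
#' baseline vertex, e.g. the corresponding location on the other
#' timepoint's anatomical surface), computes the in-plane affine map
#' between the two triangle planes, its principal stretches, and the
#' energy density described in [strain_params()]. The total is the
#' area-weighted sum over faces. Collapsed image triangles receive a large
#' finite penalty and are flagged.
#'
#' @param baseline a `surface_mesh`.
#' @param deformed_positions numeric matrix, one deformed 3-D point per
#'   baseline vertex.
#' @param params a `strain_params`.
#' @return list: `total` (sum of face area times density), `density`
#'   (per-face W), `flagged` (logical per face).
#' @export
strain_energy <- function(baseline, deformed_positions,
                          params = strain_params()) {
  rest <- rest_frame(baseline)
  f <- baseline$faces
  X <- as.matrix(deformed_positions)
  sd <- strain_face_density(rest, X[f[, 1], , drop = FALSE],
                            X[f[, 2], , drop = FALSE],
                            X[f[, 3], , drop = FALSE], params)
  list(total = sum(rest$area * sd$W), density = sd$W, flagged = sd$flagged)
}

#' Sulcal-depth proxy feature for surface matching
#'
#' The matching feature driving registration: signed radial deviation of
#' each vertex from the best-fit sphere (centered at the vertex centroid),
#' z-scored across vertices. Rotation/translation invariant. A
#' near-spherical mesh (deviation SD below `min_sd`) yields an all-zero
#' feature with a warning: there is nothing to match on.
#'
#' @param mesh a `surface_mesh`.
#' @param min_sd minimal raw SD (mm) below which the feature is zeroed.
#' @return `metric_map` (z-scored); the raw deviations (mm) are kept in
#'   attribute `"raw"`.
#' @export
compute_feature <- function(mesh, min_sd = 1e-6) {
  ctr <- colMeans(mesh$vertices)
  rel <- sweep(mesh$vertices, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  raw <- r - mean(r)
  s <- stats::sd(raw)
  if (!is.finite(s) || s < min_sd) {
    warning("near-spherical mesh: matching feature is zero (weak feature)")
    z <- rep(0, length(raw))
  } else {
    z <- (raw - mean(raw)) / s
  }
  out <- metric_map(z, mesh$name, "zscore")
  attr(out, "raw") <- raw
  out
}

control_faces_ok <- function(C, faces) {
  d <- rowSums(C[faces[, 1], , drop = FALSE] *
               cross3(C[faces[, 2], , drop = FALSE],
                      C[faces[, 3], , drop = FALSE]))
  all(d > 0)
}

sparse_bary <- function(loc, hit, n_cols) {
  f <- loc$faces[hit$face, , drop = FALSE]
  m <- nrow(f)
  Matrix::sparseMatrix(i = rep(seq_len(m), 3L),
                       j = as.vector(f),
                       x = as.vector(hit$w),
                       dims = c(m, n_cols))
}

#' Register one surface to a reference by spherical warping
#'
#' Coarse-to-fine registration of the input surface's spherical grid to the
#' reference: control-grid icosphere vertices are displaced in their tangent
#' planes (with reprojection to the sphere) by gradient descent with
#' backtracking line search on
#' mean squared feature mismatch + lambda_reg * strain energy per unit area.
#' In `"anatomical"` mode the strain is evaluated between the input
#' anatomical surface and its image on the reference anatomical surface; in
#' `"spherical"` mode (the comparator) it is evaluated between the two
#' parameter spheres. Steps that fold a control triangle or increase the
#' objective are rejected with step halving, so accepted iterations never
#' increase the objective.
#'
#' @param input,reference `surface_mesh` objects with sphere
#'   parameterizations.
#' @param params a `strain_params`.
#' @param mode "anatomical" or "spherical".
#' @param control_levels icosphere levels of the control grids, coarse to
#'   fine.
#' @param tol per-level relative objective-decrease tolerance.
#' @param max_iter maximum accepted iterations per level.
#' @param feature_in,feature_ref optional precomputed matching features.
#' @param rigid_init estimate a global rotation (Nelder-Mead on the
#'   rotation vector, feature similarity only) and use it to initialize the
#'   coarsest control grid; scan pairs share no native orientation, so this
#'   removes the bulk rotational misalignment before nonrigid matching.
#' @return a `spherical_correspondence`: list with `warped` (warped sphere
#'   position per input vertex), `face`/`w` (barycentric location on the
#'   reference grid), `control` (final control-grid positions),
#'   `diagnostics` (per-level objective traces, iterations, final
#'   similarity and strain).
#' @export
register_oneway <- function(input, reference, params = strain_params(),
                            mode = c("anatomical", "spherical"),
                            control_levels = 2:4, tol = 1e-4,
                            max_iter = 100L, feature_in = NULL,
                            feature_ref = NULL, rigid_init = TRUE) {
  mode <- match.arg(mode)
  if (is.null(input$sphere) || is.null(reference$sphere))
    stop("both meshes need sphere parameterizations")
  if (is.null(feature_in)) feature_in <- compute_feature(input)
  if (is.null(feature_ref)) feature_ref <- compute_feature(reference)
  f_in <- as.numeric(feature_in)
  f_ref <- as.numeric(feature_ref)
  data_dirs <- input$sphere
  nd <- nrow(data_dirs)
  ref_loc <- precompute_locator(reference$sphere, reference$faces)
  ref_V <- reference$vertices
  rest <- rest_frame(input)
  total_area_in <- sum(rest$area)
  fI <- input$faces

  anatomical <- mode == "anatomical"
  if (!anatomical) {
    rest_s <- rest_frame(surface_mesh(input$sphere, input$faces,
                                      validate = FALSE))
    total_area_s <- sum(rest_s$area)
  }

  objective <- function(P) {
    hit <- locate_on_sphere(ref_loc, P)
    fhat <- interp_at(ref_loc, hit, f_ref)
    sim <- mean((fhat - f_in)^2)
    if (anatomical) {
      X <- interp_at(ref_loc, hit, ref_V)
      sd <- strain_face_density(rest, X[fI[, 1], , drop = FALSE],
                                X[fI[, 2], , drop = FALSE],
                                X[fI[, 3], , drop = FALSE], params)
      strain <- sum(rest$area * sd$W) / total_area_in
    } else {
      X <- P
      sd <- strain_face_density(rest_s, X[fI[, 1], , drop = FALSE],
                                X[fI[, 2], , drop = FALSE],
                                X[fI[, 3], , drop = FALSE], params)
      strain <- sum(rest_s$area * sd$W) / total_area_s
    }
    list(value = sim + params$lambda_reg * strain, sim = sim,
         strain = strain, hit = hit, X = X, fhat = fhat)
  }

  # gradient wrt warped data positions P, with the located faces frozen
  gradient_P <- function(P, ob) {
    h <- 1e-6
    fhat0 <- ob$fhat
    X0 <- ob$X
    G_sim <- matrix(0, nd, 3)
    dX <- vector("list", 3L)
    for (k in 1:3) {
      Pk <- P
      Pk[, k] <- Pk[, k] + h
      wk <- bary_weights_for_faces(ref_loc, ob$hit$face, Pk)
      fk <- loc_face_interp(ref_loc, ob$hit$face, wk, f_ref)
      G_sim[, k] <- (fk - fhat0) / h
      if (anatomical) {
        dX[[k]] <- (loc_face_interp(ref_loc, ob$hit$face, wk, ref_V) - X0) / h
      }
    }
    resid <- ob$fhat - f_in
    G <- (2 / nd) * resid * G_sim
    # strain gradient wrt image points
    rr <- if (anatomical) rest else rest_s
    ta <- if (anatomical) total_area_in else total_area_s
    Xs <- if (anatomical) X0 else P
    GX <- strain_gradient_X(rr, fI, Xs, params, nd) / ta
    if (anatomical) {
      Gs <- matrix(0, nd, 3)
      for (k in 1:3)
        Gs[, k] <- rowSums(GX * dX[[k]])
      G <- G + params$lambda_reg * Gs
    } else {
      G <- G + params$lambda_reg * GX
    }
    G
  }

  R0 <- diag(3)
  if (rigid_init) {
    sub_i <- seq(1L, nd, by = max(1L, nd %/% 400L))
    dsub <- data_dirs[sub_i, , drop = FALSE]
    fsub <- f_in[sub_i]
    rot_obj <- function(w) {
      Rw <- rotvec_matrix(w)
      hit <- locate_on_sphere(ref_loc, dsub %*% t(Rw))
      mean((interp_at(ref_loc, hit, f_ref) - fsub)^2)
    }
    opt <- stats::optim(c(0, 0, 0), rot_obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-6))
    if (opt$value < rot_obj(c(0, 0, 0))) R0 <- rotvec_matrix(opt$par)
  }

  diagnostics <- list()
  C_prev <- NULL
  prev_grid <- NULL
  for (lev in control_levels) {
    ctrl <- make_icosphere(lev, 1)
    C <- ctrl$sphere %*% t(R0)
    if (!is.null(C_prev)) {
      ploc <- precompute_locator(prev_grid$sphere, prev_grid$faces)
      phit <- locate_on_sphere(ploc, ctrl$sphere)
      C <- interp_at(ploc, phit, C_prev)
      C <- C / sqrt(rowSums(C^2))
    }
    dloc <- precompute_locator(ctrl$sphere, ctrl$faces)
    dhit <- locate_on_sphere(dloc, data_dirs)
    Wsp <- sparse_bary(dloc, dhit, nrow(C))
    warp <- function(C) {
      Q <- as.matrix(Wsp %*% C)
      qn <- sqrt(rowSums(Q^2))
      list(P = Q / qn, qn = qn)
    }
    wp <- warp(C)
    ob <- objective(wp$P)
    trace <- ob$value
    spacing <- 1.1 / 2^lev
    step <- NULL
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      GP <- gradient_P(wp$P, ob)
      GQ <- (GP - wp$P * rowSums(GP * wp$P)) / wp$qn
      GC <- as.matrix(Matrix::crossprod(Wsp, GQ))
      GC <- GC - C * rowSums(GC * C)
      gmax <- max(sqrt(rowSums(GC^2)))
      if (gmax < 1e-12) break
      if (is.null(step)) step <- 0.2 * spacing / gmax
      accepted <- FALSE
      for (try in 1:10) {
        C_new <- C - step * GC
        C_new <- C_new / sqrt(rowSums(C_new^2))
        if (!control_faces_ok(C_new, ctrl$faces)) {
          step <- step / 2
          next
        }
        wp_new <- warp(C_new)
        ob_new <- objective(wp_new$P)
        if (ob_new$value < ob$value) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      rel <- (ob$value - ob_new$value) / max(ob$value, 1e-12)
      C <- C_new
      wp <- wp_new
      ob <- ob_new
      trace <- c(trace, ob$value)
      step <- min(step * 1.5, spacing)
      if (rel < tol) break
    }
    diagnostics[[paste0("level", lev)]] <-
      list(iterations = it, objective = trace, similarity = ob$sim,
           strain = ob$strain)
    C_prev <- C
    prev_grid <- ctrl
  }
  structure(list(warped = wp$P, face = ob$hit$face, w = ob$hit$w,
                 control = C, control_level = control_levels[length(control_levels)],
                 reference_name = reference$name, input_name = input$name,
                 mode = mode, diagnostics = diagnostics),
            class = "spherical_correspondence")
}

rotvec_matrix <- function(w) {
  a <- sqrt(sum(w^2))
  if (a < 1e-12) return(diag(3))
  rotation_matrix(w / a, a)
}

loc_face_interp <- function(loc, face_ids, w, values) {
  f <- loc$faces[face_ids, , drop = FALSE]
  if (is.matrix(values)) {
    w[, 1] * values[f[, 1], , drop = FALSE] +
      w[, 2] * values[f[, 2], , drop = FALSE] +
      w[, 3] * values[f[, 3], , drop = FALSE]
  } else {
    w[, 1] * values[f[, 1]] + w[, 2] * values[f[, 2]] +
      w[, 3] * values[f[, 3]]
  }
}

strain_gradient_X <- function(rest, faces, X, params, nv) {
  h <- 1e-6
  base <- strain_face_density(rest, X[faces[, 1], , drop = FALSE],
                              X[faces[, 2], , drop = FALSE],
                              X[faces[, 3], , drop = FALSE], params)$W
  GX <- matrix(0, nv, 3)
  Xc <- list(X[faces[, 1], , drop = FALSE],
             X[faces[, 2], , drop = FALSE],
             X[faces[, 3], , drop = FALSE])
  for (corner in 1:3) {
    for (k in 1:3) {
      Xp <- Xc
      Xp[[corner]][, k] <- Xp[[corner]][, k] + h
      Wp <- strain_face_density(rest, Xp[[1]], Xp[[2]], Xp[[3]], params)$W
      dW <- rest$area * (Wp - base) / h
      GX[, k] <- GX[, k] +
        unname(tapply_add(dW, faces[, corner], nv))
    }
  }
  GX
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx, reorder = TRUE)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Vertex-wise log2 surface-area change from a correspondence
#'
#' Maps each input-grid vertex onto the reference anatomical surface by
#' barycentric interpolation at its warped spherical location, recomputes
#' the area of every image triangle, and attributes one third of each
#' triangle's area to its vertices at both timepoints. The per-vertex map
#' is log2(image vertex area / baseline vertex area); vertices whose faces
#' are all degenerate in the image are NA.
#'
#' @param corr a `spherical_correspondence` from [register_oneway()].
#' @param baseline the input `surface_mesh` (the grid the map lives on).
#' @param reference the reference `surface_mesh`.
#' @param subdivide supersampling level: each face is split 4^k-fold (edge
#'   midpoints mapped through the warp and re-sampled on the reference
#'   surface) before measuring image areas, so the curved image region is
#'   integrated rather than approximated by one flat triangle. 0 disables.
#' @return `metric_map` of log2 area change on the baseline grid.
#' @export
area_change_from_correspondence <- function(corr, baseline, reference,
                                            subdivide = 1L) {
  ref_loc <- precompute_locator(reference$sphere, reference$faces)
  nv0 <- n_vertices(baseline)
  # subdivided copies of the baseline mesh and of the warped directions;
  # baseline midpoints are flat (sub-areas sum exactly to the face areas),
  # warped midpoints follow the piecewise-linear warp and are re-projected
  # onto the reference surface when sampled.
  v <- baseline$vertices
  f <- baseline$faces
  P <- corr$warped
  k <- as.integer(subdivide)
  while (k > 0) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- as.numeric(pmin(e[, 1], e[, 2])) * (nv + 1) + pmax(e[, 1], e[, 2])
    ued <- !duplicated(ekey)
    mid_of <- match(ekey, ekey[ued])
    v <- rbind(v, (v[e[ued, 1], , drop = FALSE] +
                   v[e[ued, 2], , drop = FALSE]) / 2)
    Pm <- (P[e[ued, 1], , drop = FALSE] + P[e[ued, 2], , drop = FALSE]) / 2
    Pm <- Pm / sqrt(rowSums(Pm^2))
    P <- rbind(P, Pm)
    nf <- nrow(f)
    m12 <- nv + mid_of[seq_len(nf)]
    m23 <- nv + mid_of[nf + seq_len(nf)]
    m31 <- nv + mid_of[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(m12, f[, 2], m23),
               cbind(m31, m23, f[, 3]),
               cbind(m12, m23, m31))
    k <- k - 1L
  }
  hit <- locate_on_sphere(ref_loc, P)
  X <- interp_at(ref_loc, hit, reference$vertices)
  fine_base <- surface_mesh(v, f, validate = FALSE)
  img <- surface_mesh(X, f, validate = FALSE)
  # fold subdivided-face areas back onto the parent faces and re-attribute
  fa1 <- suppressWarnings(face_areas(fine_base))
  fa2 <- suppressWarnings(face_areas(img))
  parent <- rep(seq_len(nrow(baseline$faces)), times = 4^subdivide)
  pf1 <- tapply_add(fa1, parent, nrow(baseline$faces))
  pf2 <- tapply_add(fa2, parent, nrow(baseline$faces))
  a1 <- numeric(nv0)
  a2 <- numeric(nv0)
  for (cidx in 1:3) {
    a1 <- a1 + tapply_add(pf1 / 3, baseline$faces[, cidx], nv0)
    a2 <- a2 + tapply_add(pf2 / 3, baseline$faces[, cidx], nv0)
  }
  out <- ifelse(a1 > 0 & a2 > 0, log2(a2 / a1), NA_real_)
  metric_map(out, baseline$name, "log2-ratio")
}

#' Bidirectional longitudinal registration of one subject
#'
#' Registers baseline to follow-up and follow-up to baseline, derives the
#' log2 surface-area change map of each direction, resamples the reverse
#' map onto the baseline grid through the forward correspondence, and
#' averages the two (with the reverse map negated) to minimize direction
#' bias. If either direction fails the result is flagged for exclusion.
#'
#' @param subject a `subject_record` (or any list with
#'   `baseline$mesh`/`followup$mesh`).
#' @param params a `strain_params`.
#' @param ... passed to [register_oneway()] (mode, control levels, ...).
#' @return a `registration_result`: list with `forward`, `reverse`,
#'   `area_change` (`metric_map` on the baseline grid), `failed`,
#'   `diagnostics`.
#' @export
register_bidirectional <- function(subject, params = strain_params(), ...) {
  b <- subject$baseline$mesh
  f <- subject$followup$mesh
  res <- try({
    fb <- compute_feature(b)
    ff <- compute_feature(f)
    fwd <- register_oneway(b, f, params, feature_in = fb,
                           feature_ref = ff, ...)
    rev <- register_oneway(f, b, params, feature_in = ff,
                           feature_ref = fb, ...)
    fwd_map <- area_change_from_correspondence(fwd, b, f)
    rev_map <- area_change_from_correspondence(rev, f, b)
    f_loc <- precompute_locator(f$sphere, f$faces)
    rev_on_base <- interp_at(f_loc, list(face = fwd$face, w = fwd$w),
                             as.numeric(rev_map))
    avg <- 0.5 * (as.numeric(fwd_map) - rev_on_base)
    list(forward = fwd, reverse = rev,
         area_change = metric_map(avg, b$name, "log2-ratio"),
         failed = FALSE,
         diagnostics = list(forward = fwd$diagnostics,
                            reverse = rev$diagnostics))
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    res <- list(forward = NULL, reverse = NULL, area_change = NULL,
                failed = TRUE, diagnostics = attr(res, "condition"))
  }
  class(res) <- "registration_result"
  res
}
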