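#' @useDynLib cortexshift, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Smooth band-limited random field on the sphere
#'
#' A stationary random field built as a sum of random plane waves
#' f(x) = sum_k a_k cos(omega_k u_k . x + phi_k) evaluated at unit vectors.
#' Amplitudes are scaled so the field has (theoretical) unit variance;
#' `correlation_length` (in the same units as `radius`) sets the dominant
#' half-wavelength. Used for pseudocortex folding, thickness variation, and
#' spatially coherent scanner noise.
#'
#' @param correlation_length spatial scale in mm on a sphere of `radius`.
#' @param radius sphere radius (mm) the angular frequencies refer to.
#' @param n_waves number of random plane waves.
#' @param seed integer seed (fields are pure functions of their parameters).
#' @return object of class `sphere_field`; evaluate with
#'   [eval_sphere_field()].
#' @export
sphere_field <- function(correlation_length, radius, n_waves = 60L,
                         seed = 1L) {
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n_waves), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ell_ang <- correlation_length / radius
    omega <- (pi / ell_ang) * stats::runif(n_waves, 0.6, 1.4)
    phase <- stats::runif(n_waves, 0, 2 * pi)
    amp <- stats::rnorm(n_waves)
  })
  amp <- amp / sqrt(sum(amp^2) / 2) # unit variance over random phase
  structure(list(u = u, omega = omega, phase = phase, amp = amp),
            class = "sphere_field")
}

#' @rdname sphere_field
#' @param field a `sphere_field`.
#' @param dirs matrix of unit vectors (rows).
#' @export
eval_sphere_field <- function(field, dirs) {
  proj <- dirs %*% t(field$u) # n x k
  ph <- sweep(sweep(proj, 2, field$omega, `*`), 2, field$phase, `+`)
  as.numeric(cos(ph) %*% field$amp)
}

#' Scanner-noise specification
#'
#' Smooth, spatially correlated perturbations standing in for segmentation
#' noise at a given field strength: a vertex displacement field (SD per
#' component, mm) and a thickness error field (SD, mm), both with the given
#' correlation length. The "1.5T" preset doubles the "3T" SDs.
#'
#' @param label "3T", "1.5T", or "none"; or pass the numeric fields
#'   directly to override.
#' @param geometry_sd mm, SD of each displacement component.
#' @param thickness_sd mm, SD of thickness error.
#' @param correlation_length mm.
#' @export
noise_spec <- function(label = c("3T", "1.5T", "none"), geometry_sd = NULL,
                       thickness_sd = NULL, correlation_length = 12) {
  label <- match.arg(label)
  base <- switch(label,
                 "3T" = c(g = 0.12, t = 0.12),
                 "1.5T" = c(g = 0.24, t = 0.24),
                 "none" = c(g = 0, t = 0))
  g <- if (is.null(geometry_sd)) base[["g"]] else geometry_sd
  th <- if (is.null(thickness_sd)) base[["t"]] else thickness_sd
  if (g < 0 || th < 0 || correlation_length <= 0)
    stop("noise SDs must be >= 0 and correlation length positive")
  structure(list(label = label, geometry_sd = g, thickness_sd = th,
                 correlation_length = correlation_length),
            class = "noise_spec")
}

#' Regional atrophy specification
#'
#' Describes the systematic two-timepoint change imposed on a synthetic
#' subject: a circular geodesic patch (center direction, angular radius,
#' raised-cosine profile) of surface-area and thickness loss, on top of
#' optional uniform global change. Values are peak log2 changes at unit
#' effect scale; per-group severity is applied as a multiplier.
#'
#' @param center unit 3-vector, patch center direction.
#' @param radius_deg angular patch radius in degrees.
#' @param peak_log2_area peak log2 surface-area change at patch center
#'   (negative = atrophy).
#' @param peak_log2_thickness peak log2 thickness change at patch center.
#' @param global_log2_area uniform log2 area change everywhere.
#' @param global_log2_thickness uniform log2 thickness change everywhere.
#' @export
atrophy_spec <- function(center = c(0, 0, 1), radius_deg = 50,
                         peak_log2_area = -0.12,
                         peak_log2_thickness = -0.12,
                         global_log2_area = -0.01,
                         global_log2_thickness = -0.01) {
  center <- center / sqrt(sum(center^2))
  vals <- c(peak_log2_area + global_log2_area,
            peak_log2_thickness + global_log2_thickness)
  if (any(abs(vals) > 1))
    stop("requested |log2 change| > 1 is unrealistically large; refused")
  structure(list(center = center, radius = radius_deg * pi / 180,
                 peak_log2_area = peak_log2_area,
                 peak_log2_thickness = peak_log2_thickness,
                 global_log2_area = global_log2_area,
                 global_log2_thickness = global_log2_thickness),
            class = "atrophy_spec")
}

patch_profile <- function(theta, radius) {
  ifelse(theta < radius, 0.5 * (1 + cos(pi * theta / radius)), 0)
}

#' Target log2-change fields of an atrophy spec
#'
#' @param spec an `atrophy_spec`.
#' @param dirs unit direction per vertex.
#' @param effect effect-scale multiplier.
#' @return list with per-vertex `area` and `thickness` target log2 changes.
#' @export
atrophy_targets <- function(spec, dirs, effect = 1) {
  theta <- acos(pmin(1, pmax(-1, dirs %*% spec$center)))
  h <- patch_profile(as.numeric(theta), spec$radius)
  list(area = effect * (spec$global_log2_area + spec$peak_log2_area * h),
       thickness = effect * (spec$global_log2_thickness +
                             spec$peak_log2_thickness * h))
}

#' Folded pseudocortex surface
#'
#' Deforms an icosphere radially by a smooth band-limited random field to
#' create sulcus/gyrus-like folds, returning both the anatomical mesh and
#' its unit-sphere parameterization (same topology). Radial deformation of
#' a star-shaped surface cannot self-intersect; excessive bumpiness that
#' would collapse the radius is refused.
#'
#' @param level icosphere subdivision level.
#' @param radius mean radius (mm); the default 80 mm gives a sphere area in
#'   the range of a human hemisphere midthickness surface (~8e4 mm^2).
#' @param bumpiness fractional radial modulation amplitude in [0, 1).
#' @param fold_scale correlation length of the folding field (mm).
#' @param seed integer; the surface is a pure function of its arguments.
#' @return `surface_mesh` with `sphere` parameterization, `ico` ancestry,
#'   and a `radial` element recording the generative radius function.
#' @export
make_pseudocortex <- function(level = 4L, radius = 80, bumpiness = 0.06,
                              fold_scale = 25, seed = 1L) {
  if (bumpiness < 0 || bumpiness >= 1) stop("bumpiness must be in [0, 1)")
  ico <- make_icosphere(level, radius = 1)
  dirs <- ico$sphere
  if (bumpiness == 0) {
    r <- rep(radius, nrow(dirs))
    fld <- NULL
  } else {
    fld <- sphere_field(fold_scale, radius, n_waves = 80L, seed = seed)
    f <- eval_sphere_field(fld, dirs)
    f <- pmax(pmin(f, 2.5), -2.5)
    r <- radius * (1 + bumpiness * f)
    if (any(r < 0.05 * radius)) stop("bumpiness too high: radius collapses")
  }
  m <- surface_mesh(dirs * r, ico$faces,
                    name = sprintf("pseudocortex%d", level),
                    sphere = dirs, validate = FALSE)
  m$ico <- ico$ico
  m$radial <- list(field = fld, radius = radius, bumpiness = bumpiness,
                   clip = 2.5)
  m
}

pseudocortex_radius_at <- function(radial, dirs) {
  if (is.null(radial$field)) return(rep(radial$radius, nrow(dirs)))
  f <- eval_sphere_field(radial$field, dirs)
  f <- pmax(pmin(f, radial$clip), -radial$clip)
  radial$radius * (1 + radial$bumpiness * f)
}

# Radially symmetric angular remap. Inside the patch the map satisfies
# cos(theta') = 1 - int_0^theta s(t) sin(t) dt with s = 2^(patch log2
# area), whose induced area scale equals s(theta) exactly. The angular
# deficit accumulated at the patch edge is then released smoothly
# (smoothstep) over an annulus of half the patch radius, so the map is the
# identity beyond 1.5x the patch radius: atrophy stays local, with a mild
# compensating expansion ring around the patch.
patch_theta_map <- function(spec, effect, n_grid = 4096L) {
  rp <- spec$radius
  ro <- min(1.5 * rp, pi - 0.2)
  t <- seq(0, rp, length.out = n_grid)
  s <- 2^(effect * spec$peak_log2_area * patch_profile(t, rp))
  integrand <- s * sin(t)
  cum <- c(0, cumsum((integrand[-1] + integrand[-n_grid]) / 2 * diff(t)))
  ctp <- pmin(1, pmax(-1, 1 - cum))
  tp <- acos(ctp)
  delta_p <- rp - tp[n_grid] # angular deficit at the patch edge
  fwd <- function(theta) {
    out <- stats::approx(t, tp, xout = pmin(theta, rp), rule = 2)$y
    ann <- theta > rp & theta < ro
    u <- (ro - theta[ann]) / (ro - rp)
    out[ann] <- theta[ann] - delta_p * (3 * u^2 - 2 * u^3)
    out[theta >= ro] <- theta[theta >= ro]
    out
  }
  tg <- seq(0, pi, length.out = n_grid)
  tpg <- fwd(tg)
  inv <- function(theta_p) stats::approx(tpg, tg, xout = theta_p,
                                         rule = 2)$y
  list(fwd = fwd, inv = inv)
}

# rotate directions along great circles through `center`, from angular
# distance theta to new_theta, keeping the azimuth
move_toward <- function(dirs, center, new_theta) {
  cost <- pmin(1, pmax(-1, as.numeric(dirs %*% center)))
  perp <- dirs - outer(cost, center)
  pn <- sqrt(rowSums(perp^2))
  ok <- pn > 1e-12
  perp[ok, ] <- perp[ok, ] / pn[ok]
  perp[!ok, ] <- 0
  out <- outer(cos(new_theta), center) + sin(new_theta) * perp
  out / sqrt(rowSums(out^2))
}

# Scanner noise model: geometry noise displaces the surface radially (the
# star-shaped analog of boundary-placement error along the surface normal);
# thickness noise is an independent smooth field.
noise_fields <- function(noise, radius, seed) {
  list(radial = sphere_field(noise$correlation_length, radius, n_waves = 50L,
                             seed = seed + 1L),
       thick = sphere_field(noise$correlation_length, radius, n_waves = 50L,
                            seed = seed + 4L))
}

eval_noise <- function(fields, noise, dirs) {
  list(disp = (noise$geometry_sd * eval_sphere_field(fields$radial, dirs)) *
         dirs,
       thick = noise$thickness_sd * eval_sphere_field(fields$thick, dirs))
}

apply_noise <- function(mesh, thickness, noise, seed) {
  if (noise$geometry_sd == 0 && noise$thickness_sd == 0)
    return(list(mesh = mesh, thickness = thickness))
  dirs <- mesh$sphere
  R <- mean(sqrt(rowSums(mesh$vertices^2)))
  nf <- noise_fields(noise, R, seed)
  nz <- eval_noise(nf, noise, dirs)
  m2 <- mesh
  m2$vertices <- mesh$vertices + nz$disp
  th <- pmin(pmax(thickness + nz$thick, 0.55), 5.95)
  list(mesh = m2, thickness = th)
}

#' Impose known atrophy on a baseline pseudocortex
#'
#' Builds the follow-up surface by a smooth material deformation of the
#' baseline: vertices slide toward the patch center along great circles of
#' the parameter sphere under an angular remap whose induced area scale
#' equals the target field exactly (up to mesh discretization), carrying
#' their fold height with them; a uniform global area change is applied as
#' a radial scale. Thickness changes multiplicatively by the target field.
#' Ground truth is then *measured* from the known one-to-one vertex
#' correspondence of the clean (noise-free) surfaces, and independent
#' smooth scanner noise is added on top.
#'
#' @param baseline mesh from [make_pseudocortex()].
#' @param thickness baseline thickness map (mm).
#' @param spec an `atrophy_spec`.
#' @param noise a `noise_spec` (applied to the follow-up scan only; add
#'   baseline scan noise separately).
#' @param effect effect-scale multiplier for this subject.
#' @param seed integer seed for the noise fields.
#' @param thickness_fn optional function(dirs) returning the baseline
#'   thickness field at arbitrary unit directions (must reproduce
#'   `thickness` on the baseline grid); enables exact resampling of the
#'   follow-up on a new grid.
#' @return list: `mesh` (follow-up, same grid), `thickness`, `truth`
#'   (per-vertex realized log2 `area`, `thickness`, `volume` change of the
#'   clean deformation), and — when the baseline is a pseudocortex —
#'   `analytic`: functions `point(dirs)`, `thickness(dirs)` and
#'   `orig_dir(dirs)` evaluating the noisy follow-up surface exactly at
#'   arbitrary parameter directions.
#' @export
apply_atrophy <- function(baseline, thickness, spec, noise = noise_spec("none"),
                          effect = 1, seed = 1L, thickness_fn = NULL) {
  if (is.null(baseline$sphere)) stop("baseline must carry a sphere")
  dirs <- baseline$sphere
  targ <- atrophy_targets(spec, dirs, effect)
  if (any(abs(targ$area) > 1) || any(abs(targ$thickness) > 1))
    stop("requested |log2 change| > 1 is unrealistically large; refused")
  has_patch <- spec$peak_log2_area != 0 && effect != 0
  if (has_patch) {
    tmaps <- patch_theta_map(spec, effect)
    contract <- function(d) {
      th <- acos(pmin(1, pmax(-1, as.numeric(d %*% spec$center))))
      move_toward(d, spec$center, tmaps$fwd(th))
    }
    uncontract <- function(d) {
      thp <- acos(pmin(1, pmax(-1, as.numeric(d %*% spec$center))))
      move_toward(d, spec$center, tmaps$inv(thp))
    }
  } else {
    contract <- uncontract <- identity
  }
  new_dirs <- contract(dirs)
  gscale <- 2^(effect * spec$global_log2_area / 2)
  r_material <- sqrt(rowSums(baseline$vertices^2))
  clean_v <- new_dirs * (r_material * gscale)
  clean <- baseline
  clean$vertices <- clean_v
  clean$sphere <- new_dirs
  clean$name <- paste0(baseline$name, ".followup")
  thick_clean <- thickness * 2^(targ$thickness)
  truth_area <- log2(as.numeric(vertex_areas(clean)) /
                     as.numeric(vertex_areas(baseline)))
  truth_thick <- targ$thickness
  mean_r <- if (!is.null(baseline$radial)) baseline$radial$radius else
    mean(r_material)
  nf <- noise_fields(noise, mean_r, seed)
  noisy_mesh <- clean
  noisy_thick <- thick_clean
  if (noise$geometry_sd > 0 || noise$thickness_sd > 0) {
    nz <- eval_noise(nf, noise, new_dirs)
    noisy_mesh$vertices <- clean_v + nz$disp
    noisy_thick <- pmin(pmax(thick_clean + nz$thick, 0.55), 5.95)
  }
  out <- list(mesh = noisy_mesh, thickness = noisy_thick,
              truth = list(area = truth_area, thickness = truth_thick,
                           volume = truth_area + truth_thick))
  if (!is.null(baseline$radial)) {
    radial <- baseline$radial
    thick_at <- if (!is.null(thickness_fn)) thickness_fn else
      function(d) rep(mean(thickness), nrow(d))
    tau_at <- function(d) atrophy_targets(spec, d, effect)$thickness
    out$analytic <- list(
      orig_dir = uncontract,
      point = function(d) {
        d0 <- uncontract(d)
        p <- d * (pseudocortex_radius_at(radial, d0) * gscale)
        if (noise$geometry_sd > 0)
          p <- p + eval_noise(nf, noise, d)$disp
        p
      },
      thickness = function(d) {
        d0 <- uncontract(d)
        th <- thick_at(d0) * 2^(tau_at(d0))
        if (noise$thickness_sd > 0)
          th <- pmin(pmax(th + noise$thickness_sd *
                            eval_sphere_field(nf$thick, d), 0.55), 5.95)
        th
      })
  }
  out
}
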