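# Synthetic phantoms with closed-form volumes: single tapered legs,
# fused leg pairs with a medial thigh bridge, whole-body phantoms standing on
# a turntable disc, scan-noise perturbations, hole injection, and the full
# simulated repeated-scan precision study. Every generator returns (or can
# compute) its own analytic ground truth; no phantom exists without one.

#' Phantom specification
#'
#' A parametric leg/body phantom. The per-leg cross-section at height z is an
#' ellipse with semi-axes `a(z)`, `b(z)` interpolated linearly between profile
#' knots; the optional `cx` column leans the leg axis medially (feet apart,
#' thighs converging) without changing slice areas, so the closed-form volume
#' `pi * integral of a(z) b(z) dz` (piecewise cubic, evaluated exactly by
#' Simpson's rule per interval) is unaffected.
#'
#' @param profile Data frame of knots with columns `z`, `a`, `b` (mm) and
#'   optionally `cx` (distance of the leg centre from the midline, mm).
#' @param inter_foot_distance Distance between foot centres, mm (default 400,
#'   the standardized turntable foot positioning).
#' @param fusion `NULL` for separate legs, or `list(z_start, z_end,
#'   halfwidth)`: a medial bridge of half-height `halfwidth` (mm in y) joining
#'   the legs over `[z_start, z_end]`. Radius and centre offset must be
#'   constant and circular over the fusion band.
#' @param segments Angular resolution of each ring (default 128).
#' @param ring_spacing Maximum z spacing of rings, mm (default 40; between
#'   knots the surface is ruled so this does not bias the volume).
#' @param seed Seed for any randomized use of the spec.
#' @return A list of class `legvol_phantom_spec`.
#' @export
phantom_spec <- function(profile = slim_leg_profile(), inter_foot_distance = 400,
                         fusion = NULL, segments = 128, ring_spacing = 40,
                         seed = 1) {
  check_profile(profile)
  if (!"cx" %in% names(profile)) profile$cx <- inter_foot_distance / 2
  if (!is.null(fusion)) {
    stopifnot(all(c("z_start", "z_end", "halfwidth") %in% names(fusion)),
              fusion$z_start < fusion$z_end, fusion$halfwidth > 0)
  }
  structure(list(profile = profile, inter_foot_distance = inter_foot_distance,
                 fusion = fusion, segments = as.integer(segments),
                 ring_spacing = ring_spacing, seed = seed),
            class = "legvol_phantom_spec")
}

#' Built-in leg profiles
#'
#' `slim_leg_profile()` is a leg with fully visible medial surfaces (complete
#' workflow, ~7.5 L in the default crop band); `stout_leg_profile()` is a
#' high-BMI leg whose thighs nearly touch at the midline (limited workflow,
#' ~14 L). Knots: ankle, calf, thigh onset, infragluteal region.
#'
#' @return A profile data frame for [phantom_spec()].
#' @export
slim_leg_profile <- function() {
  data.frame(z = c(0, 300, 650, 850),
             a = c(38, 45, 65, 65),
             b = c(38, 45, 65, 65),
             cx = c(200, 190, 140, 140))
}

#' @rdname slim_leg_profile
#' @export
stout_leg_profile <- function() {
  data.frame(z = c(0, 300, 640, 850),
             a = c(45, 60, 95, 95),
             b = c(45, 60, 95, 95),
             cx = c(200, 180, 100, 100))
}

#' Default fusion band for the stout profile
#' @return A fusion list for [phantom_spec()].
#' @export
stout_fusion <- function() list(z_start = 640, z_end = 780, halfwidth = 35)

# ---- analytic volumes -------------------------------------------------------

#' Closed-form volume of a profile leg
#'
#' `pi * integral of a(z) b(z) dz` over `[z0, z1]`; with linear knots the
#' integrand is piecewise quadratic, so per-interval Simpson evaluation is
#' exact.
#'
#' @param profile Profile data frame (`z`, `a`, `b`).
#' @param z0,z1 Integration limits, mm (defaults: full profile range).
#' @return Volume in mL.
#' @export
leg_profile_volume <- function(profile, z0 = NULL, z1 = NULL) {
  check_profile(profile)
  z0 <- max(z0 %||% min(profile$z), min(profile$z))
  z1 <- min(z1 %||% max(profile$z), max(profile$z))
  if (z1 <= z0) return(0)
  zs <- sort(unique(c(z0, z1, profile$z[profile$z > z0 & profile$z < z1])))
  f <- function(z) {
    p <- profile_at(profile, z)
    p$a * p$b
  }
  total <- 0
  for (i in seq_len(length(zs) - 1L)) {
    h <- zs[i + 1L] - zs[i]
    total <- total + h / 6 * (f(zs[i]) + 4 * f((zs[i] + zs[i + 1L]) / 2) + f(zs[i + 1L]))
  }
  pi * total / 1000
}

# Cross-section area added by the medial bridge: rectangle 2c x 2w minus the
# two circular bites (circle/strip overlap), mm^2. Requires w < r < c.
bridge_extra_area <- function(r, c_off, w) {
  stopifnot(w < r, r < c_off + r)  # geometric sanity; overlap formula needs w < r
  4 * c_off * w - 2 * (w * sqrt(r^2 - w^2) + r^2 * asin(w / r))
}

# Fusion geometry actually realized by the mesh: the bridge half-height snaps
# to the angular grid so bridge walls and shelf share ring vertices exactly.
fusion_geometry <- function(spec) {
  fu <- spec$fusion
  if (is.null(fu)) return(NULL)
  pr <- spec$profile
  at <- function(z) profile_at(pr, z)
  p1 <- at(fu$z_start); p2 <- at(fu$z_end)
  inner <- pr[pr$z > fu$z_start & pr$z < fu$z_end, , drop = FALSE]
  band_ok <- abs(p1$a - p2$a) < 1e-9 && abs(p1$a - p1$b) < 1e-9 &&
    abs(p2$a - p2$b) < 1e-9 && abs(p1$cx - p2$cx) < 1e-9 &&
    all(abs(inner$a - p1$a) < 1e-9) && all(abs(inner$b - p1$a) < 1e-9) &&
    all(abs(inner$cx - p1$cx) < 1e-9)
  if (!band_ok) {
    legvol_abort("fusion band requires a circular, constant profile (a = b, cx constant)",
                 "legvol_spec_error")
  }
  r <- p1$a
  c_off <- p1$cx
  if (r >= c_off) legvol_abort("legs overlap: thigh radius must be below the centre offset",
                               "legvol_spec_error")
  np <- spec$segments
  if (np %% 2L != 0L) legvol_abort("fused phantoms need an even segment count",
                                   "legvol_spec_error")
  k <- round(asin(min(fu$halfwidth, 0.9 * r) / r) * np / (2 * pi))
  k <- max(1L, min(as.integer(k), np %/% 4L - 1L))
  theta0 <- 2 * pi * k / np
  list(z_start = fu$z_start, z_end = fu$z_end, r = r, c_off = c_off,
       k = k, theta0 = theta0, w = r * sin(theta0))
}

#' Analytic per-leg truth for a phantom in a crop band
#'
#' For separate legs this is the profile integral; for fused phantoms the
#' per-leg truth is defined as the flat-capped half-space volume (everything
#' on that leg's side of the median sagittal plane) -- exactly the target the
#' limited-visibility workflow estimates. The un-fused twin volume (without
#' the bridge share) is also returned so the flat-fill bias is quantifiable.
#'
#' @param spec A [phantom_spec()].
#' @param z0,z1 Crop band, mm (defaults: full leg).
#' @return Tibble with `side`, `truth_ml`, `twin_ml`.
#' @export
phantom_truth <- function(spec, z0 = NULL, z1 = NULL) {
  v_leg <- leg_profile_volume(spec$profile, z0, z1)
  extra <- 0
  geo <- fusion_geometry(spec)
  if (!is.null(geo)) {
    lo <- max(z0 %||% -Inf, geo$z_start)
    hi <- min(z1 %||% Inf, geo$z_end)
    if (hi > lo) {
      extra <- bridge_extra_area(geo$r, geo$c_off, geo$w) * (hi - lo) / 1000
    }
  }
  tibble::tibble(side = c("left", "right"),
                 truth_ml = v_leg + extra / 2,
                 twin_ml = v_leg)
}

# ---- single leg -------------------------------------------------------------

#' Generate a single leg phantom
#'
#' Closed elliptical generalized cylinder with flat end caps.
#'
#' @param spec A [phantom_spec()].
#' @param side `"left"` (x > 0) or `"right"`.
#' @return List with `mesh` (`legvol_mesh`) and `analytic_volume` (mL, exact).
#' @export
make_leg_phantom <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  sgn <- if (side == "left") 1 else -1
  pr <- spec$profile
  pr$cx <- sgn * pr$cx
  mesh <- mesh_generalized_cylinder(pr, segments = spec$segments,
                                    ring_spacing = spec$ring_spacing,
                                    name = paste0(side, "_leg"))
  list(mesh = mesh, analytic_volume = leg_profile_volume(spec$profile))
}

# ---- fused pair -------------------------------------------------------------

#' Generate a fused leg pair
#'
#' Two legs joined by a medial bridge over the fusion band, built symmetric
#' about x = 0 as a single edge-connected surface. The per-leg truths are the
#' flat-capped half-space volumes (x > 0 and x < 0) of the fused solid,
#' computed in closed form from the construction.
#'
#' @param spec A [phantom_spec()] with `fusion` set.
#' @return List with `mesh`, `left_truth`, `right_truth` (mL) and
#'   `total_truth` (mL).
#' @export
make_fused_pair <- function(spec) {
  geo <- fusion_geometry(spec)
  if (is.null(geo)) legvol_abort("spec has no fusion band", "legvol_spec_error")
  pr <- spec$profile
  np <- spec$segments
  k <- geo$k
  theta <- ring_angles(np)
  r <- geo$r; c_off <- geo$c_off; w <- geo$w
  z1 <- geo$z_start; z2 <- geo$z_end
  L <- max(pr$z)

  env <- new.env(parent = emptyenv())
  env$verts <- vector("list", 0)
  env$n <- 0L
  add_pts <- function(m) {
    env$verts[[length(env$verts) + 1L]] <- m
    ids <- env$n + seq_len(nrow(m))
    env$n <- env$n + nrow(m)
    ids
  }
  faces <- list()
  add_faces <- function(f) faces[[length(faces) + 1L]] <<- f

  circle_ring <- function(z, sgn) {
    p <- profile_at(pr, z)
    add_pts(cbind(sgn * p$cx + p$a * cos(theta), p$b * sin(theta), z))
  }

  # arc index subsets within a circle ring (1-based positions into theta)
  idx_wrap <- function(v) ((v - 1L) %% np) + 1L
  r_lat <- idx_wrap((k + 1L):(np - k + 1L))             # right leg lateral arc, CCW
  l_lat <- idx_wrap((np / 2 + 1L + k):(np + np / 2 + 1L - k))  # left leg lateral arc, CCW
  r_med_desc <- idx_wrap((k + 1L):(k + 1L - 2L * k))    # theta0 down to -theta0
  l_med_desc <- idx_wrap((np / 2 + 1L + k):(np / 2 + 1L - k))  # pi+theta0 down to pi-theta0

  # bridge segment interior x positions (junction at +/- (c - r cos theta0))
  xj <- c_off - r * cos(geo$theta0)
  gap <- 2 * xj
  nb <- max(0L, as.integer(round(gap / (2 * pi * r / np))) - 1L)
  seg_x <- if (nb > 0) seq(-xj, xj, length.out = nb + 2L)[2:(nb + 1L)] else numeric(0)

  bridge_pts <- function(z) {
    bot <- if (nb > 0) add_pts(cbind(seg_x, -w, z)) else integer(0)       # +x order
    top <- if (nb > 0) add_pts(cbind(rev(seg_x), w, z)) else integer(0)   # -x order
    list(bot = bot, top = top)
  }

  # fused union-boundary ring: R lateral arc, bottom segment (+x), L lateral
  # arc, top segment (-x); counter-clockwise viewed from +z
  fused_ring_ids <- function(right_ring, left_ring, br) {
    c(right_ring[r_lat], br$bot, left_ring[l_lat], br$top)
  }

  levels_below <- profile_levels(sort(unique(c(pr$z[pr$z < z1], z1))), spec$ring_spacing)
  levels_above <- profile_levels(sort(unique(c(z2, pr$z[pr$z > z2]))), spec$ring_spacing)
  n_band <- max(1L, ceiling((z2 - z1) / spec$ring_spacing))
  levels_band <- seq(z1, z2, length.out = n_band + 1L)
  levels_band <- levels_band[-c(1L, length(levels_band))]

  ring_r_below <- lapply(levels_below, circle_ring, sgn = -1)
  ring_l_below <- lapply(levels_below, circle_ring, sgn = 1)
  ring_r_above <- lapply(levels_above, circle_ring, sgn = -1)
  ring_l_above <- lapply(levels_above, circle_ring, sgn = 1)

  # walls below and above the band, plus flat foot and top caps
  nbel <- length(levels_below)
  for (i in seq_len(nbel - 1L)) {
    add_faces(stitch_rings_idx(ring_r_below[[i]], ring_r_below[[i + 1L]]))
    add_faces(stitch_rings_idx(ring_l_below[[i]], ring_l_below[[i + 1L]]))
  }
  nab <- length(levels_above)
  for (i in seq_len(nab - 1L)) {
    add_faces(stitch_rings_idx(ring_r_above[[i]], ring_r_above[[i + 1L]]))
    add_faces(stitch_rings_idx(ring_l_above[[i]], ring_l_above[[i + 1L]]))
  }
  cap_ring <- function(ring_ids, z_is_top) {
    pts <- do.call(rbind, env$verts)[ring_ids, , drop = FALSE]
    apex <- add_pts(matrix(colMeans(pts), 1))
    add_faces(fan_cap_idx(ring_ids, apex, top = z_is_top))
  }
  cap_ring(ring_r_below[[1L]], FALSE)
  cap_ring(ring_l_below[[1L]], FALSE)
  cap_ring(ring_r_above[[nab]], TRUE)
  cap_ring(ring_l_above[[nab]], TRUE)

  # composite fused rings at the band ends share arc vertices with the circle
  # rings, so the horizontal shelf closes the transition exactly
  br1 <- bridge_pts(z1)
  br2 <- bridge_pts(z2)
  fused1 <- fused_ring_ids(ring_r_below[[nbel]], ring_l_below[[nbel]], br1)
  fused2 <- fused_ring_ids(ring_r_above[[1L]], ring_l_above[[1L]], br2)
  band_rings <- lapply(levels_band, function(z) {
    rr <- circle_ring(z, -1)
    ll <- circle_ring(z, 1)
    fused_ring_ids(rr, ll, bridge_pts(z))
  })
  chain <- c(list(fused1), band_rings, list(fused2))
  for (i in seq_len(length(chain) - 1L)) {
    add_faces(stitch_rings_idx(chain[[i]], chain[[i + 1L]]))
  }

  # shelves: bridge footprint minus the two circular bites, a simple polygon
  shelf_polygon <- function(right_ring, left_ring, br) {
    c(right_ring[r_med_desc], br$bot, left_ring[l_med_desc], br$top)
  }
  shelf_faces <- function(poly_ids, flip) {
    pts <- do.call(rbind, env$verts)[poly_ids, 1:2, drop = FALSE]
    tris <- ear_clip(pts)
    if (is.null(tris)) legvol_abort("shelf polygon triangulation failed",
                                    "legvol_internal_error")
    f <- matrix(poly_ids[tris], ncol = 3)
    if (flip) f[, c(1, 3, 2)] else f
  }
  add_faces(shelf_faces(shelf_polygon(ring_r_below[[nbel]], ring_l_below[[nbel]], br1),
                        flip = TRUE))   # bottom shelf, outward -z
  add_faces(shelf_faces(shelf_polygon(ring_r_above[[1L]], ring_l_above[[1L]], br2),
                        flip = FALSE))  # top shelf, outward +z

  verts <- do.call(rbind, env$verts)
  mesh <- compact_mesh(triangle_mesh(verts, do.call(rbind, faces), name = "fused_legs"))

  v_leg <- leg_profile_volume(pr)
  extra <- bridge_extra_area(r, c_off, w) * (z2 - z1) / 1000
  list(mesh = mesh,
       left_truth = v_leg + extra / 2,
       right_truth = v_leg + extra / 2,
       total_truth = 2 * v_leg + extra,
       bridge_halfwidth = w)
}

# ---- whole body -------------------------------------------------------------

turntable_disc <- function(radius = 450, thickness = 20, segments = 64,
                           n_radial = 6) {
  theta <- ring_angles(segments)
  circ <- function(r, z) cbind(r * cos(theta), r * sin(theta), z)
  verts <- list()
  add <- function(m) {
    verts[[length(verts) + 1L]] <<- m
    sum(vapply(verts, nrow, 0L)) - nrow(m) + seq_len(nrow(m))
  }
  bottom_rim <- add(circ(radius, -thickness))
  radii <- radius * seq_len(n_radial) / n_radial
  top_rings <- lapply(radii, function(r) add(circ(r, 0)))
  bc <- add(matrix(c(0, 0, -thickness), 1))
  tc <- add(matrix(c(0, 0, 0), 1))
  faces <- list(
    fan_cap_idx(bottom_rim, bc, top = FALSE),
    stitch_rings_idx(bottom_rim, top_rings[[n_radial]]),
    fan_cap_idx(top_rings[[1L]], tc, top = TRUE))
  for (i in seq_len(n_radial - 1L)) {
    # coplanar inner/outer rings: outer ring first so the normals point +z
    faces[[length(faces) + 1L]] <- stitch_rings_idx(top_rings[[i + 1L]], top_rings[[i]])
  }
  triangle_mesh(do.call(rbind, verts), do.call(rbind, faces), name = "turntable")
}

torso_block <- function(z0 = 860, z1 = 1500, a = 160, b = 100,
                        anterior_offset = -25, segments = 64) {
  profile <- data.frame(z = c(z0, z1), a = a, b = b)
  m <- mesh_generalized_cylinder(profile, segments = segments, ring_spacing = 80,
                                 name = "torso")
  m$vertices[, 2] <- m$vertices[, 2] + anterior_offset
  m
}

merge_meshes <- function(meshes, name = NULL) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), 0L)))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$faces + offs[i]))
  triangle_mesh(verts, faces, name = name)
}

#' Generate a whole-body phantom
#'
#' Turntable disc (top at z = 0), two legs at half the inter-foot distance
#' from the midline (fused when the spec has a fusion band), and a simple
#' elliptical torso with an anterior centroid offset so the facing direction
#' is recoverable. Optionally pre-transformed by a recorded rigid motion,
#' which the orientation module should invert.
#'
#' @param spec A [phantom_spec()].
#' @param transform Optional `legvol_rigid` applied to the assembled phantom
#'   (the recorded ground-truth motion).
#' @return List with `mesh`, `truth` (per-leg crop-free truth tibble from
#'   [phantom_truth()]) and `transform`.
#' @export
make_whole_body_phantom <- function(spec, transform = NULL) {
  legs <- if (!is.null(spec$fusion)) {
    make_fused_pair(spec)$mesh
  } else {
    merge_meshes(list(make_leg_phantom(spec, "left")$mesh,
                      make_leg_phantom(spec, "right")$mesh))
  }
  mesh <- merge_meshes(list(turntable_disc(), legs, torso_block()),
                       name = "whole_body_phantom")
  if (!is.null(transform)) mesh <- transform_mesh(mesh, transform)
  list(mesh = mesh, truth = phantom_truth(spec), transform = transform)
}

# ---- noise and defects ------------------------------------------------------

#' Scan-noise specification
#'
#' Vertex-wise isotropic jitter plus a small random rigid motion, emulating
#' measurement noise and subject repositioning between repeated scans.
#'
#' @param vertex_jitter_sd Isotropic per-vertex jitter SD, mm (default 0.5).
#' @param reposition_rotation_sd Rotation SD, degrees (default 2).
#' @param reposition_translation_sd Translation SD per axis, mm (default 10).
#' @return A list of class `legvol_noise_spec`.
#' @export
noise_spec <- function(vertex_jitter_sd = 0.5, reposition_rotation_sd = 2,
                       reposition_translation_sd = 10) {
  stopifnot(vertex_jitter_sd >= 0, reposition_rotation_sd >= 0,
            reposition_translation_sd >= 0)
  structure(list(vertex_jitter_sd = vertex_jitter_sd,
                 reposition_rotation_sd = reposition_rotation_sd,
                 reposition_translation_sd = reposition_translation_sd),
            class = "legvol_noise_spec")
}

#' Perturb a scan
#'
#' Applies vertex jitter then a random rigid motion about the mesh centroid.
#' Deterministic per seed; zero noise returns the identical mesh.
#'
#' @param mesh A `legvol_mesh`.
#' @param noise A [noise_spec()].
#' @param seed Mandatory seed for any nonzero noise.
#' @return The perturbed `legvol_mesh`.
#' @export
perturb_scan <- function(mesh, noise = noise_spec(), seed) {
  any_noise <- noise$vertex_jitter_sd > 0 || noise$reposition_rotation_sd > 0 ||
    noise$reposition_translation_sd > 0
  if (!any_noise) return(mesh)
  if (missing(seed) || is.null(seed)) {
    legvol_abort("a seed is mandatory for nonzero noise", "legvol_domain_error")
  }
  with_seed(seed, {
    v <- mesh$vertices
    if (noise$vertex_jitter_sd > 0) {
      v <- v + matrix(stats::rnorm(length(v), sd = noise$vertex_jitter_sd), ncol = 3)
    }
    g <- colMeans(v)
    axis <- stats::rnorm(3)
    angle <- stats::rnorm(1, sd = noise$reposition_rotation_sd)
    shift <- stats::rnorm(3, sd = noise$reposition_translation_sd)
    rot <- rotation_axis_angle(axis, angle)
    v <- sweep(sweep(v, 2, g) %*% t(rot), 2, g + shift, "+")
    mesh$vertices <- v
    mesh
  })
}

#' Inject a surface hole
#'
#' Removes all faces whose centroids lie within `radius` of `center`,
#' emulating an occlusion defect.
#'
#' @param mesh A `legvol_mesh`.
#' @param center Numeric 3-vector, mm.
#' @param radius Hole radius, mm (0 leaves the mesh unchanged).
#' @return The holed `legvol_mesh`.
#' @export
inject_hole <- function(mesh, center, radius) {
  if (radius <= 0) return(mesh)
  f <- mesh$faces
  ctr <- (mesh$vertices[f[, 1], , drop = FALSE] +
            mesh$vertices[f[, 2], , drop = FALSE] +
            mesh$vertices[f[, 3], , drop = FALSE]) / 3
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 + (ctr[, 3] - center[3])^2
  keep <- d2 > radius^2
  if (all(keep)) return(mesh)
  subset_faces(mesh, keep)
}

# ---- simulated precision study ----------------------------------------------

#' Simulate a repeated-scan precision study
#'
#' Generates `n_subjects` whole-body phantoms (a BMI-driven mixture of
#' separated and fused leg morphologies), two noise-perturbed scans each, and
#' the analytic ground-truth leg volumes for the crop band -- everything the
#' full pipeline and cohort analysis need, with no external data.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param noise A [noise_spec()] applied independently to each scan.
#' @param seed Master seed; all randomness derives from it.
#' @param crop The [crop_config()] used for every subject.
#' @param segments Angular phantom resolution.
#' @return A list of class `legvol_study`: `subjects` (tibble), `scans`
#'   (per-subject list of two meshes), `truth` (tibble `subject_id`, `side`,
#'   `truth_ml`, `twin_ml`), `crop`, `noise`, `seed`.
#' @export
simulate_precision_study <- function(n_subjects = 20, noise = noise_spec(),
                                     seed = 1, crop = crop_config(70, 810),
                                     segments = 128) {
  demo <- with_seed(seed, {
    bmi <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      repeat {
        x <- stats::rnorm(1, 32.3, 9.7)
        if (x >= 18.5 && x <= 56) { bmi[i] <- x; break }
      }
    }
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      age = pmin(80, pmax(18, round(stats::rnorm(n_subjects, 41, 12)))),
      sex = sample(c("female", "male"), n_subjects, replace = TRUE,
                   prob = c(0.78, 0.22)),
      bmi = round(bmi, 1))
  })
  demo$bmi_class <- classify_bmi(demo$bmi)
  demo$variant <- ifelse(demo$bmi >= 30, "limited", "complete")

  scans <- vector("list", n_subjects)
  truths <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    spec <- subject_phantom_spec(demo$bmi[i], demo$variant[i], segments)
    body <- make_whole_body_phantom(spec)
    s1 <- perturb_scan(body$mesh, noise, seed = seed * 1000 + i * 10 + 1)
    s2 <- perturb_scan(body$mesh, noise, seed = seed * 1000 + i * 10 + 2)
    scans[[i]] <- list(s1, s2)
    tr <- phantom_truth(spec, crop$z_low, crop$z_high)
    tr$subject_id <- demo$subject_id[i]
    truths[[i]] <- tr
  }
  structure(list(subjects = demo, scans = scans,
                 truth = dplyr::bind_rows(truths)[, c("subject_id", "side",
                                                      "truth_ml", "twin_ml")],
                 crop = crop, noise = noise, seed = seed),
            class = "legvol_study")
}

# Subject-level phantom spec: template profile by workflow variant, scaled in
# cross-section with BMI; fused thighs sit 10 mm apart regardless of scale.
subject_phantom_spec <- function(bmi, variant, segments = 128) {
  if (variant == "limited") {
    pr <- stout_leg_profile()
    s <- sqrt(bmi / 36)
    pr$a <- pr$a * s
    pr$b <- pr$b * s
    r_thigh <- pr$a[length(pr$a)]
    c_off <- r_thigh + 5
    pr$cx <- c(200, 180, c_off, c_off)
    fu <- stout_fusion()
    fu$halfwidth <- 0.35 * r_thigh
    phantom_spec(pr, fusion = fu, segments = segments)
  } else {
    pr <- slim_leg_profile()
    s <- sqrt(bmi / 26)
    pr$a <- pr$a * s
    pr$b <- pr$b * s
    phantom_spec(pr, segments = segments)
  }
}

#' @export
print.legvol_study <- function(x, ...) {
  cat(sprintf("<legvol_study: %d subjects (%d complete, %d limited), seed %s>\n",
              nrow(x$subjects), sum(x$subjects$variant == "complete"),
              sum(x$subjects$variant == "limited"), format(x$seed)))
  invisible(x)
}
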