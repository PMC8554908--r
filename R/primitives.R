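# Basic closed solids. Rings are ordered counter-clockwise viewed from +z so
# that stitched walls and fan caps give outward normals and positive volume.

#' Axis-aligned cube mesh
#' @param side Edge length, mm.
#' @param center Numeric 3-vector, mm.
#' @return A watertight `legvol_mesh` with 8 vertices and 12 faces.
#' @export
mesh_cube <- function(side = 100, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  f <- matrix(c(
    1, 3, 2, 2, 3, 4,   # bottom (z-)
    5, 6, 7, 6, 8, 7,   # top (z+)
    1, 2, 5, 2, 6, 5,   # front (y-)
    3, 7, 4, 4, 7, 8,   # back (y+)
    1, 5, 3, 3, 5, 7,   # left (x-)
    2, 4, 6, 4, 8, 6    # right (x+)
  ), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f, name = "cube")
}

#' Latitude/longitude sphere mesh
#' @param radius Radius, mm.
#' @param n_theta Angular segments around the axis.
#' @param n_phi Latitudinal bands.
#' @param center Numeric 3-vector, mm.
#' @return A watertight `legvol_mesh`.
#' @export
mesh_uv_sphere <- function(radius = 100, n_theta = 48, n_phi = 24,
                           center = c(0, 0, 0)) {
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  phi <- pi * seq_len(n_phi - 1) / n_phi  # interior latitudes, pole to pole
  rings <- lapply(phi, function(p) {  # from south upward
    cbind(radius * sin(p) * cos(theta),
          radius * sin(p) * sin(theta),
          -radius * cos(p))
  })
  build_ring_solid(rings, center = center,
                   bottom_apex = c(0, 0, -radius), top_apex = c(0, 0, radius),
                   name = "sphere")
}

#' Right circular cylinder mesh
#' @param radius Radius, mm.
#' @param height Height, mm (base at z = 0).
#' @param segments Angular segments.
#' @param n_rings Number of ring levels along z (>= 2).
#' @param center_xy Axis position in the xy plane.
#' @return A watertight `legvol_mesh`.
#' @export
mesh_cylinder <- function(radius = 50, height = 400, segments = 64,
                          n_rings = 2, center_xy = c(0, 0)) {
  profile <- data.frame(z = c(0, height), a = radius, b = radius)
  mesh_generalized_cylinder(profile, segments = segments,
                            ring_spacing = height / max(1, n_rings - 1),
                            center_xy = center_xy, name = "cylinder")
}

#' Elliptical generalized cylinder from a piecewise-linear profile
#'
#' Cross-section at height z is an ellipse with semi-axes `a(z)`, `b(z)`
#' interpolated linearly between knots; the optional `cx(z)` column shears the
#' axis in x (slice areas, and hence volume, are unaffected by the shear).
#'
#' @param profile Data frame with columns `z`, `a`, `b` and optionally `cx`
#'   (knots, strictly increasing in `z`, semi-axes positive, mm).
#' @param segments Angular segments of each ring.
#' @param ring_spacing Maximum z spacing between rings; knots are always
#'   included (between knots the surface is ruled, so spacing does not affect
#'   the enclosed volume).
#' @param center_xy Offset added to every ring centre.
#' @param name Mesh name.
#' @return A watertight `legvol_mesh` with flat end caps.
#' @export
mesh_generalized_cylinder <- function(profile, segments = 128,
                                      ring_spacing = 40, center_xy = c(0, 0),
                                      name = NULL) {
  check_profile(profile)
  zs <- profile_levels(profile$z, ring_spacing)
  theta <- ring_angles(segments)
  rings <- lapply(zs, function(z) {
    p <- profile_at(profile, z)
    cbind(center_xy[1] + p$cx + p$a * cos(theta),
          center_xy[2] + p$b * sin(theta),
          z)
  })
  build_ring_solid(rings, name = name)
}

check_profile <- function(profile) {
  if (!all(c("z", "a", "b") %in% names(profile))) {
    legvol_abort("profile needs columns z, a, b", "legvol_spec_error")
  }
  if (any(diff(profile$z) <= 0)) {
    legvol_abort("profile knots must be strictly increasing in z", "legvol_spec_error")
  }
  if (any(profile$a <= 0 | profile$b <= 0)) {
    legvol_abort("profile semi-axes must be positive", "legvol_spec_error")
  }
  invisible(profile)
}

profile_levels <- function(knots, ring_spacing) {
  zs <- unlist(lapply(seq_len(length(knots) - 1), function(i) {
    n <- max(1L, ceiling((knots[i + 1] - knots[i]) / ring_spacing))
    seq(knots[i], knots[i + 1], length.out = n + 1L)[-(n + 1L)]
  }))
  c(zs, knots[length(knots)])
}

profile_at <- function(profile, z) {
  list(a = stats::approx(profile$z, profile$a, z, rule = 2)$y,
       b = stats::approx(profile$z, profile$b, z, rule = 2)$y,
       cx = if ("cx" %in% names(profile))
         stats::approx(profile$z, profile$cx, z, rule = 2)$y else 0)
}

ring_angles <- function(segments) 2 * pi * (seq_len(segments) - 1) / segments

# ---- assembly helpers -------------------------------------------------------

# Stitch two rings given as vertex-index vectors of equal length; skips
# degenerate triangles (repeated indices), which arise when rings share
# vertices. Lower ring first.
stitch_rings_idx <- function(lower, upper) {
  k <- length(lower)
  j2 <- c(2:k, 1L)
  f <- rbind(cbind(lower, lower[j2], upper[j2]),
             cbind(lower, upper[j2], upper))
  f[f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3], , drop = FALSE]
}

# Triangle fan closing a ring against an apex/centroid vertex index.
# `top = TRUE` for a cap whose outward normal points along +stacking direction.
fan_cap_idx <- function(ring, apex, top) {
  k <- length(ring)
  j2 <- c(2:k, 1L)
  if (top) cbind(apex, ring, ring[j2]) else cbind(apex, ring[j2], ring)
}

# Build a closed solid from a list of k-point rings (matrices, low z first),
# capped with centroid fans (or supplied apexes).
build_ring_solid <- function(rings, center = c(0, 0, 0),
                             bottom_apex = NULL, top_apex = NULL, name = NULL) {
  k <- nrow(rings[[1]])
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  idx <- lapply(seq_len(nr), function(i) (i - 1L) * k + seq_len(k))
  faces <- list()
  for (i in seq_len(nr - 1L)) {
    faces[[length(faces) + 1L]] <- stitch_rings_idx(idx[[i]], idx[[i + 1L]])
  }
  bot <- bottom_apex %||% colMeans(rings[[1]])
  top <- top_apex %||% colMeans(rings[[nr]])
  verts <- rbind(verts, bot, top)
  bi <- nrow(verts) - 1L
  ti <- nrow(verts)
  faces[[length(faces) + 1L]] <- fan_cap_idx(idx[[1]], bi, top = FALSE)
  faces[[length(faces) + 1L]] <- fan_cap_idx(idx[[nr]], ti, top = TRUE)
  v <- sweep(verts, 2, center, "+")
  triangle_mesh(v, do.call(rbind, faces), name = name)
}
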