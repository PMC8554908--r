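# Surface repair: flat-plane hole filling (least-squares plane fit of the
# boundary loop, projection, ear-clipping triangulation, lift back to the
# original loop vertices), planar capping of crop boundaries, spike-edge
# removal and small-hole filling. The goal of repair is a watertight,
# consistently oriented leg segment fit for divergence-theorem volumetry.

#' Repair parameters
#'
#' @param small_hole_max_edges Boundary loops with at most this many edges are
#'   treated as small occlusion holes and filled (default 25).
#' @param spike_edge_factor A vertex is a spike candidate when one of its
#'   incident edges exceeds this multiple of the median edge length
#'   (default 4).
#' @param spike_normal_angle Normal deviation (degrees) beyond which a spike
#'   candidate is removed (default 70).
#' @param planarity_tol Distance tolerance (mm) for treating a boundary loop
#'   as lying in a crop plane (default 1).
#' @return A list of class `legvol_repair_params`.
#' @export
repair_params <- function(small_hole_max_edges = 25, spike_edge_factor = 4,
                          spike_normal_angle = 70, planarity_tol = 1) {
  stopifnot(small_hole_max_edges > 0, spike_edge_factor > 0,
            spike_normal_angle > 0, spike_normal_angle < 180, planarity_tol > 0)
  structure(list(small_hole_max_edges = small_hole_max_edges,
                 spike_edge_factor = spike_edge_factor,
                 spike_normal_angle = spike_normal_angle,
                 planarity_tol = planarity_tol),
            class = "legvol_repair_params")
}

#' Plane specification
#'
#' A plane `{p : normal . p = offset}` with a unit normal.
#'
#' @param normal Numeric 3-vector (normalized internally).
#' @param offset Signed distance along the normal, mm.
#' @param inlier_count Supporting vertex count (for fitted planes).
#' @return A list of class `legvol_plane`.
#' @export
plane_spec <- function(normal, offset, inlier_count = NA_integer_) {
  len <- sqrt(sum(normal^2))
  if (len == 0) legvol_abort("zero plane normal", "legvol_domain_error")
  structure(list(normal = normal / len, offset = offset / len,
                 inlier_count = inlier_count),
            class = "legvol_plane")
}

# ---- ear clipping -----------------------------------------------------------

# Triangulate a simple polygon given as an n x 2 matrix. Output triangles are
# index triples in the polygon's own traversal orientation. Returns NULL when
# no ear can be found (e.g. a self-intersecting projected polygon); callers
# fall back to a centroid fan.
ear_clip <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(NULL)
  if (n == 3L) return(matrix(1:3, 1))
  idx <- seq_len(n)
  x <- pts[, 1]; y <- pts[, 2]
  area2 <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  orient <- if (area2 >= 0) 1 else -1
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  eps <- 1e-12 * max(scale2, 1)
  tris <- matrix(0L, n - 2L, 3L)
  k <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    found <- FALSE
    for (i in seq_len(m)) {
      ip <- idx[if (i == 1L) m else i - 1L]
      ic <- idx[i]
      inx <- idx[if (i == m) 1L else i + 1L]
      cross <- (x[ic] - x[ip]) * (y[inx] - y[ic]) - (y[ic] - y[ip]) * (x[inx] - x[ic])
      if (orient * cross <= eps) next  # reflex or degenerate corner
      others <- setdiff(idx, c(ip, ic, inx))
      if (length(others) && any(point_in_tri(x[others], y[others],
                                             x[ip], y[ip], x[ic], y[ic],
                                             x[inx], y[inx], orient))) next
      k <- k + 1L
      tris[k, ] <- c(ip, ic, inx)
      idx <- idx[-i]
      found <- TRUE
      break
    }
    if (!found) {
      # no strict ear: clip a collinear corner (zero-area triangle, leaves the
      # polygon geometrically unchanged) so collinear chains stay connected
      for (i in seq_len(m)) {
        ip <- idx[if (i == 1L) m else i - 1L]
        ic <- idx[i]
        inx <- idx[if (i == m) 1L else i + 1L]
        cross <- (x[ic] - x[ip]) * (y[inx] - y[ic]) - (y[ic] - y[ip]) * (x[inx] - x[ic])
        if (abs(cross) <= eps) {
          k <- k + 1L
          tris[k, ] <- c(ip, ic, inx)
          idx <- idx[-i]
          found <- TRUE
          break
        }
      }
    }
    guard <- guard + 1L
    if (!found || guard > 4L * n) return(NULL)
  }
  k <- k + 1L
  tris[k, ] <- idx
  tris[seq_len(k), , drop = FALSE]
}

point_in_tri <- function(px, py, ax, ay, bx, by, cx, cy, orient) {
  d1 <- orient * ((bx - ax) * (py - ay) - (by - ay) * (px - ax))
  d2 <- orient * ((cx - bx) * (py - by) - (cy - by) * (px - bx))
  d3 <- orient * ((ax - cx) * (py - cy) - (ay - cy) * (px - cx))
  d1 > 0 & d2 > 0 & d3 > 0
}

# ---- flat fill --------------------------------------------------------------

# Distance of loop vertices from a plane; used to match loops to crop planes.
loop_plane_distance <- function(mesh, loop, plane) {
  max(abs(as.numeric(mesh$vertices[loop, , drop = FALSE] %*% plane$normal) - plane$offset))
}

# Fill one boundary loop: least-squares plane (or a supplied plane), project,
# ear clip, lift back to the original loop vertices. The loop order produced
# by boundary_loops() already opposes the adjacent face windings, so emitted
# faces keep the mesh consistently oriented. Falls back to a centroid fan
# (with a warning) when the projected polygon cannot be ear-clipped.
fill_loop <- function(mesh, loop, plane = NULL) {
  if (length(loop) < 3L) return(mesh)
  p <- mesh$vertices[loop, , drop = FALSE]
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  if (is.null(plane)) {
    sv <- svd(q, nu = 0)
    basis <- sv$v[, 1:2, drop = FALSE]
  } else {
    nrm <- plane$normal
    e1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    basis <- cbind(e1, e2)
  }
  uv <- q %*% basis
  tris <- ear_clip(uv)
  if (is.null(tris)) {
    rlang::warn("projected hole polygon is not simple; falling back to centroid fan",
                class = "legvol_fill_fallback")
    nv <- nrow(mesh$vertices)
    mesh$vertices <- rbind(mesh$vertices, ctr)
    k <- length(loop)
    new_faces <- cbind(loop, loop[c(2:k, 1L)], nv + 1L)
  } else {
    new_faces <- matrix(loop[tris], ncol = 3)
  }
  mesh$faces <- rbind(mesh$faces, new_faces)
  mesh
}

#' Flat-plane hole filling
#'
#' Closes every boundary loop (optionally excluding loops that lie in given
#' planes, e.g. crop planes that will be capped later) with a planar patch:
#' least-squares plane fit to the loop, projection onto that plane,
#' ear-clipping triangulation of the projected polygon, and lift back to the
#' original loop vertices. For a loop that is exactly planar the fill is
#' volume-neutral relative to the flat cap.
#'
#' @param mesh A `legvol_mesh` with boundary loops.
#' @param params A [repair_params()].
#' @param skip_planes Optional list of [plane_spec()] objects; loops within
#'   `params$planarity_tol` of one of them are left open.
#' @return The mesh with the selected loops closed.
#' @export
fill_holes_flat <- function(mesh, params = repair_params(), skip_planes = NULL) {
  loops <- boundary_loops(mesh)
  for (loop in loops) {
    if (length(loop) < 3L) next
    if (!is.null(skip_planes)) {
      near <- vapply(skip_planes, function(pl)
        loop_plane_distance(mesh, loop, pl) <= params$planarity_tol, TRUE)
      if (any(near)) next
    }
    mesh <- fill_loop(mesh, loop)
  }
  mesh
}

#' Cap boundary loops lying in given planes
#'
#' Loops coplanar (within `tol`) with one of `planes` are capped exactly in
#' that plane; other loops are left open and reported via an attribute.
#'
#' @param mesh A `legvol_mesh`.
#' @param planes List of [plane_spec()] objects (e.g. the two crop planes).
#' @param tol Planarity tolerance, mm.
#' @return The capped mesh; attribute `open_loops` counts loops left open.
#' @export
cap_planar_boundaries <- function(mesh, planes, tol = 1) {
  loops <- boundary_loops(mesh)
  open_left <- 0L
  for (loop in loops) {
    if (length(loop) < 3L) next
    dists <- vapply(planes, function(pl) loop_plane_distance(mesh, loop, pl), 0)
    if (min(dists) <= tol) {
      mesh <- fill_loop(mesh, loop, plane = planes[[which.min(dists)]])
    } else {
      open_left <- open_left + 1L
    }
  }
  attr(mesh, "open_loops") <- open_left
  mesh
}

#' Fill small boundary loops
#'
#' Loops with at most `params$small_hole_max_edges` edges are closed by the
#' flat fill; larger loops are untouched.
#'
#' @inheritParams fill_holes_flat
#' @return The mesh with small holes closed.
#' @export
fill_small_holes <- function(mesh, params = repair_params()) {
  loops <- boundary_loops(mesh)
  for (loop in loops) {
    if (length(loop) >= 3L && length(loop) <= params$small_hole_max_edges) {
      mesh <- fill_loop(mesh, loop)
    }
  }
  mesh
}

#' Remove spike-edge artifacts
#'
#' Deletes vertices displaced far off the surface: the *shortest* incident
#' edge must exceed `spike_edge_factor` times the local (1-ring
#' neighbourhood) median edge length (a spike vertex is far from all of its
#' neighbours, whereas the neighbours themselves keep their short lateral
#' edges), and at least one incident-face normal must deviate more than
#' `spike_normal_angle` degrees from the mean surrounding normal. The
#' resulting holes are re-closed by the flat fill when small enough.
#' Legitimate sharp features and anisotropic but regular meshing pass through
#' unchanged.
#'
#' @inheritParams fill_holes_flat
#' @return The repaired mesh; attribute `spikes_removed` gives the count.
#' @export
remove_spikes <- function(mesh, params = repair_params()) {
  v <- mesh$vertices
  f <- mesh$faces
  de <- directed_edges(f)
  el <- sqrt(rowSums((v[de[, 1], , drop = FALSE] - v[de[, 2], , drop = FALSE])^2))
  vmin <- rep(Inf, nrow(v))
  agg <- tapply(el, de[, 1], min)
  vmin[as.integer(names(agg))] <- agg
  # global pre-filter, then confirm against the local 1-ring median edge
  cand <- which(is.finite(vmin) &
                  vmin > params$spike_edge_factor * stats::median(el))
  if (length(cand) == 0L) {
    attr(mesh, "spikes_removed") <- 0L
    return(mesh)
  }
  fn <- face_normals(v, f)
  incident <- lapply(cand, function(vi) which(f[, 1] == vi | f[, 2] == vi | f[, 3] == vi))
  spikes <- vapply(seq_along(cand), function(k) {
    own <- incident[[k]]
    if (length(own) == 0L) return(FALSE)
    nbrs <- setdiff(unique(as.vector(f[own, ])), cand[k])
    ring <- which(matrix(f %in% nbrs, ncol = 3) |> rowSums() > 0)
    around <- setdiff(ring, own)
    if (length(around) == 0L) return(FALSE)
    ring_edges <- el[de[, 1] %in% unique(as.vector(f[around, ]))]
    if (vmin[cand[k]] <= params$spike_edge_factor * stats::median(ring_edges)) {
      return(FALSE)
    }
    n_around <- colMeans(fn[around, , drop = FALSE])
    n_around <- n_around / max(sqrt(sum(n_around^2)), 1e-12)
    dev <- acos(pmin(1, pmax(-1, fn[own, , drop = FALSE] %*% n_around))) * 180 / pi
    max(dev) > params$spike_normal_angle
  }, TRUE)
  bad_v <- cand[spikes]
  if (length(bad_v) == 0L) {
    attr(mesh, "spikes_removed") <- 0L
    return(mesh)
  }
  keep <- !(f[, 1] %in% bad_v | f[, 2] %in% bad_v | f[, 3] %in% bad_v)
  out <- subset_faces(mesh, keep)
  out <- fill_small_holes(out, params)
  attr(out, "spikes_removed") <- length(bad_v)
  out
}

face_normals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  n / ifelse(len > 0, len, 1)
}

#' Full repair pipeline for a cropped leg segment
#'
#' Fixed order: spike-edge removal (before any filling, so large patch
#' triangles are never mistaken for spikes), flat fill of the sagittal cut and
#' occlusion holes (crop-plane loops excluded), small-hole filling, then
#' planar capping of the crop boundaries. The output is checked to be
#' watertight.
#'
#' @param mesh Cropped (and, for the limited workflow, sagittally split)
#'   `legvol_mesh`.
#' @param crop The subject's [crop_config()].
#' @param params A [repair_params()].
#' @return A watertight, consistently oriented `legvol_mesh`.
#' @export
repair_segment <- function(mesh, crop, params = repair_params()) {
  crop_planes <- list(plane_spec(c(0, 0, 1), crop$z_low),
                      plane_spec(c(0, 0, 1), crop$z_high))
  mesh <- remove_spikes(mesh, params)
  mesh <- fill_holes_flat(mesh, params, skip_planes = crop_planes)
  mesh <- fill_small_holes(mesh, params)
  mesh <- cap_planar_boundaries(mesh, crop_planes, tol = params$planarity_tol)
  rep <- inspect_mesh(mesh)
  if (!rep$is_watertight) {
    legvol_abort(sprintf("repair left %d open boundary loop(s)",
                         length(rep$boundary_loops)), "legvol_open_mesh_error")
  }
  orient_mesh(mesh)
}
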