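# Scan orientation: detect the flat turntable surface, move it onto the z = 0
# transverse plane at the origin, then rotate about z so the body faces the
# frontal plane. Canonical frame: z superior, x = subject's left (positive),
# y posterior (positive), millimetres throughout.
#
# The original workflow aligned scans manually in a GUI; here the alignment is
# automated (RANSAC plane consensus + torso PCA) with a manual facing mode, so
# the procedure is deterministic and reproducible.

#' Detect the turntable support plane
#'
#' Robust plane fit (consensus over random 3-point hypotheses, refined by a
#' total-least-squares fit on the inliers) restricted to the lowest fraction
#' of vertices along the current gravity axis. The returned normal points
#' toward the body centroid.
#'
#' @param mesh A `legvol_mesh`, roughly upright (z up).
#' @param lowest_fraction Fraction of vertices (lowest z) considered
#'   (default 0.05).
#' @param ransac_iters Random hypotheses drawn (default 500).
#' @param inlier_tol Inlier distance tolerance, mm (default 1, matching the
#'   ~1 mm scan resolution).
#' @param seed RNG seed for the hypothesis draws.
#' @param min_inliers Minimum supporting vertices (default 100).
#' @param min_inlier_fraction Minimum supported share of the candidate set
#'   (default 0.25; the turntable only occupies part of the low region).
#' @return A [plane_spec()] with `inlier_count` set.
#' @export
detect_support_plane <- function(mesh, lowest_fraction = 0.05, ransac_iters = 500,
                                 inlier_tol = 1, seed = 1, min_inliers = 100,
                                 min_inlier_fraction = 0.25) {
  validate_mesh(mesh)
  stopifnot(lowest_fraction > 0, lowest_fraction <= 1)
  v <- mesh$vertices
  zcut <- stats::quantile(v[, 3], lowest_fraction, names = FALSE)
  cand <- v[v[, 3] <= zcut, , drop = FALSE]
  n <- nrow(cand)
  if (n < 3L) legvol_abort("too few low vertices for a support plane fit",
                           "legvol_no_support_plane")
  best <- NULL
  best_count <- -1L
  with_seed(seed, {
    for (it in seq_len(ransac_iters)) {
      pick <- sample.int(n, 3L)
      p <- cand[pick, , drop = FALSE]
      u <- p[2, ] - p[1, ]
      w <- p[3, ] - p[1, ]
      nrm <- c(u[2] * w[3] - u[3] * w[2],
               u[3] * w[1] - u[1] * w[3],
               u[1] * w[2] - u[2] * w[1])
      len <- sqrt(sum(nrm^2))
      if (len < 1e-9) next
      nrm <- nrm / len
      d <- as.numeric(cand %*% nrm) - sum(nrm * p[1, ])
      count <- sum(abs(d) <= inlier_tol)
      if (count > best_count) {
        best_count <- count
        best <- list(normal = nrm, offset = sum(nrm * p[1, ]))
      }
    }
  })
  if (is.null(best) || best_count < max(min_inliers, min_inlier_fraction * n)) {
    legvol_abort(sprintf(
      "no support plane: best consensus %d of %d candidate vertices",
      max(best_count, 0L), n), "legvol_no_support_plane")
  }
  # refine: iterated total least squares with inlier reselection over the
  # whole mesh, so a tilted consensus hypothesis (whose inlier band only
  # covers part of the support surface) converges onto the full surface
  # instead of a biased strip, and no low-z truncation biases the fit
  nrm <- best$normal
  off <- best$offset
  for (iter in 1:5) {
    d <- as.numeric(v %*% nrm) - off
    inl <- v[abs(d) <= inlier_tol, , drop = FALSE]
    if (nrow(inl) < 3L) break
    ctr <- colMeans(inl)
    sv <- svd(sweep(inl, 2, ctr), nu = 0)
    new_nrm <- sv$v[, 3]
    if (sum(new_nrm * nrm) < 0) new_nrm <- -new_nrm
    converged <- sum(new_nrm * nrm) > 1 - 1e-10 &&
      abs(sum(new_nrm * ctr) - off) < 1e-6
    nrm <- new_nrm
    off <- sum(nrm * ctr)
    if (converged) break
  }
  # orient toward the body
  if (sum(nrm * colMeans(v)) - off < 0) {
    nrm <- -nrm
    off <- -off
  }
  d2 <- as.numeric(v %*% nrm) - off
  plane_spec(nrm, off, inlier_count = sum(abs(d2) <= inlier_tol))
}

#' Align the support plane to the transverse origin plane
#'
#' Returns the moved mesh together with the rigid transform that maps the
#' detected plane onto z = 0 with the body in z > 0 and the plane-inlier
#' centroid at x = y = 0, so the same motion can be reapplied to other data.
#'
#' @param mesh A `legvol_mesh`.
#' @param plane A [plane_spec()] from [detect_support_plane()].
#' @param inlier_tol Tolerance used to recover the inlier centroid, mm.
#' @return List with elements `mesh` and `transform` (`legvol_rigid`).
#' @export
align_to_origin <- function(mesh, plane, inlier_tol = 1) {
  v <- mesh$vertices
  rot <- rotation_between(plane$normal, c(0, 0, 1))
  d <- as.numeric(v %*% plane$normal) - plane$offset
  inl <- v[abs(d) <= inlier_tol, , drop = FALSE]
  if (nrow(inl) == 0L) inl <- matrix(plane$offset * plane$normal, 1)
  # recentre on the horizontal bounding-box midpoint of the support-surface
  # inliers (the turntable centre): robust to which inliers survive the
  # distance threshold, unlike their centroid
  inl_rot <- inl %*% t(rot)
  ctr <- c((max(inl_rot[, 1]) + min(inl_rot[, 1])) / 2,
           (max(inl_rot[, 2]) + min(inl_rot[, 2])) / 2,
           mean(inl_rot[, 3]))
  trans <- rigid_transform(rot, -ctr)
  out <- transform_mesh(mesh, trans)
  if (mean(out$vertices[, 3]) <= 0) {
    legvol_abort("body lies below the support plane after alignment",
                 "legvol_internal_error")
  }
  list(mesh = out, transform = trans)
}

#' Rotate the body to face the frontal plane
#'
#' Axial (about z) rotation only. In `pca_torso` mode the principal axis of
#' the torso cross-section in the given z slab is mapped to the x (left-right)
#' axis; the anterior sign is resolved by the slab centroid's offset from the
#' vertical axis (the anterior protrusion of the torso), with a `manual` mode
#' as override.
#'
#' @param mesh A `legvol_mesh` already aligned to the z = 0 support plane.
#' @param method `"pca_torso"` or `"manual"`.
#' @param slab_z_range Height window (mm) of the torso slab; default the
#'   60-85% band of the mesh height.
#' @param manual_angle Rotation to apply (degrees, about z) in manual mode.
#' @param axis_ratio_min Minimum PCA eigenvalue ratio below which the section
#'   is considered isotropic and an ambiguous-orientation error is raised.
#' @return List with elements `mesh`, `transform` and `angle` (the applied
#'   rotation, degrees).
#' @export
face_frontal <- function(mesh, method = c("pca_torso", "manual"),
                         slab_z_range = NULL, manual_angle = 0,
                         axis_ratio_min = 1.2) {
  method <- match.arg(method)
  if (method == "manual") {
    trans <- rigid_transform(rotation_z(manual_angle))
    return(list(mesh = transform_mesh(mesh, trans), transform = trans,
                angle = manual_angle))
  }
  v <- mesh$vertices
  if (is.null(slab_z_range)) {
    zmax <- max(v[, 3])
    slab_z_range <- c(0.60, 0.85) * zmax
  }
  slab <- v[v[, 3] >= slab_z_range[1] & v[, 3] <= slab_z_range[2], 1:2, drop = FALSE]
  if (nrow(slab) < 10L) {
    legvol_abort("torso slab contains no geometry", "legvol_empty_result")
  }
  ctr <- colMeans(slab)
  cv <- stats::cov(slab)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] < axis_ratio_min * eg$values[2]) {
    legvol_abort(
      "torso cross-section is isotropic; axial orientation is ambiguous - use method = 'manual'",
      "legvol_ambiguous_orientation")
  }
  axis <- eg$vectors[, 1]
  angle <- atan2(axis[2], axis[1])  # rotate by -angle to map axis onto x
  rot <- rotation_z(-angle * 180 / pi)
  # anterior-sign resolution: the slab centroid protrudes anteriorly (y < 0)
  ctr_rot <- as.numeric(rot %*% c(ctr, 0))
  if (abs(ctr_rot[2]) < 1e-6) {
    legvol_abort(
      "anterior direction is ambiguous (centroid on the hip axis) - use method = 'manual'",
      "legvol_ambiguous_orientation")
  }
  if (ctr_rot[2] > 0) rot <- rotation_z(180) %*% rot
  trans <- rigid_transform(rot)
  deg <- atan2(rot[2, 1], rot[1, 1]) * 180 / pi
  list(mesh = transform_mesh(mesh, trans), transform = trans, angle = deg)
}

#' Full scan orientation
#'
#' Convenience wrapper: support-plane detection, alignment to the origin, and
#' frontal facing. Idempotent on an already-aligned scan (up to numerical
#' tolerance) and volume-preserving (rigid motions only).
#'
#' @param mesh A `legvol_mesh`.
#' @param seed RANSAC seed.
#' @param ... Passed to [face_frontal()].
#' @inheritParams detect_support_plane
#' @return List with elements `mesh` and `transform` (the composed motion).
#' @export
orient_scan <- function(mesh, seed = 1, inlier_tol = 1, ...) {
  plane <- detect_support_plane(mesh, seed = seed, inlier_tol = inlier_tol)
  al <- align_to_origin(mesh, plane, inlier_tol = inlier_tol)
  fc <- face_frontal(al$mesh, ...)
  list(mesh = fc$mesh, transform = compose_transforms(fc$transform, al$transform))
}
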