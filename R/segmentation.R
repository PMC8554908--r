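# Leg segmentation: exact plane clipping between the two anatomical
# transverse planes, connected-component extraction, complete-vs-limited
# visibility classification, and the median-sagittal split of fused legs.

#' Crop configuration for a subject
#'
#' The two transverse crop planes (heights in mm over the turntable origin
#' plane) and the median sagittal plane coordinate. The same configuration is
#' applied to both repeated scans of a subject so legs are cropped
#' reproducibly.
#'
#' @param z_low Height of the lateral malleolus plane (lower crop), mm.
#' @param z_high Height of the infragluteal fold plane (upper crop), mm.
#' @param sagittal_x Median sagittal plane x coordinate, mm (default 0, the
#'   turntable centre in the canonical frame).
#' @return A list of class `legvol_crop`.
#' @export
crop_config <- function(z_low, z_high, sagittal_x = 0) {
  if (!(z_low >= 0 && z_low < z_high)) {
    legvol_abort("crop requires 0 <= z_low < z_high", "legvol_domain_error")
  }
  structure(list(z_low = z_low, z_high = z_high, sagittal_x = sagittal_x),
            class = "legvol_crop")
}

# ---- exact plane clipping ---------------------------------------------------

#' Split a mesh by an arbitrary plane, exactly
#'
#' Splits a mesh by the plane `{p : normal . p = offset}`. Triangles crossing
#' the plane are cut along the intersection segment; both halves share the
#' newly created cut vertices (computed once per edge), so the capped volumes
#' of the two halves are exactly complementary up to floating point. A vertex
#' exactly on the plane belongs to both halves.
#'
#' The returned halves are open along the cut; close them with
#' [fill_holes_flat()] or [cap_planar_boundaries()] before measuring volume.
#'
#' @param mesh A `legvol_mesh`.
#' @param normal Plane normal (length-3 numeric, need not be unit).
#' @param offset Plane offset so that the plane is `normal . p = offset`.
#' @param eps Distances within `eps` of the plane count as on the plane.
#' @return A list with open meshes `above` and `below`.
#' @export
split_by_plane <- function(mesh, normal, offset, eps = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.numeric(v %*% normal) - offset
  d[abs(d) < eps] <- 0
  s <- sign(d)
  sf <- matrix(s[f], ncol = 3)
  n_pos <- rowSums(sf > 0)
  n_neg <- rowSums(sf < 0)
  above_only <- n_neg == 0L
  below_only <- n_pos == 0L & n_neg > 0L
  mixed <- which(n_pos > 0L & n_neg > 0L)

  new_v <- list()
  edge_cache <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  cut_point <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    new_v[[length(new_v) + 1L]] <<- p
    id <- nv0 + length(new_v)
    edge_cache[[key]] <- id
    id
  }

  fa_extra <- list()
  fb_extra <- list()
  for (fi in mixed) {
    tri <- f[fi, ]
    pa <- integer(0)
    pb <- integer(0)
    for (k in 1:3) {
      u <- tri[k]
      w <- tri[if (k == 3L) 1L else k + 1L]
      if (s[u] >= 0) pa <- c(pa, u)
      if (s[u] <= 0) pb <- c(pb, u)
      if (s[u] * s[w] < 0) {
        cp <- cut_point(u, w)
        pa <- c(pa, cp)
        pb <- c(pb, cp)
      }
    }
    if (length(pa) >= 3L) {
      fa_extra[[length(fa_extra) + 1L]] <-
        cbind(pa[1], pa[2:(length(pa) - 1L)], pa[3:length(pa)])
    }
    if (length(pb) >= 3L) {
      fb_extra[[length(fb_extra) + 1L]] <-
        cbind(pb[1], pb[2:(length(pb) - 1L)], pb[3:length(pb)])
    }
  }

  all_v <- if (length(new_v)) rbind(v, do.call(rbind, new_v)) else v
  make_half <- function(whole, extra) {
    faces <- rbind(f[whole, , drop = FALSE],
                   if (length(extra)) do.call(rbind, extra))
    if (is.null(faces) || nrow(faces) == 0L) return(NULL)
    faces <- faces[faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
                     faces[, 1] != faces[, 3], , drop = FALSE]
    if (nrow(faces) == 0L) return(NULL)
    compact_mesh(triangle_mesh(all_v, faces, name = mesh$name, validate = FALSE))
  }
  list(above = make_half(above_only, fa_extra),
       below = make_half(below_only, fb_extra))
}

#' Crop a mesh between two transverse planes
#'
#' Exact clip: triangles crossing either plane are split along the
#' intersection segment; the result is open at both cut planes.
#'
#' @param mesh An aligned `legvol_mesh` (canonical frame, z up).
#' @param crop A [crop_config()].
#' @return The open cropped `legvol_mesh`.
#' @export
crop_transverse <- function(mesh, crop) {
  stopifnot(inherits(crop, "legvol_crop"))
  upper <- split_by_plane(mesh, c(0, 0, 1), crop$z_low)$above
  if (is.null(upper)) {
    legvol_abort("crop band contains no geometry", "legvol_empty_result")
  }
  band <- split_by_plane(upper, c(0, 0, 1), crop$z_high)$below
  if (is.null(band)) {
    legvol_abort("crop band contains no geometry", "legvol_empty_result")
  }
  band
}

#' Edge-connected components of a cropped mesh
#'
#' Components are sorted by descending face count; fragments below
#' `min_faces` (scan-noise debris) are discarded.
#'
#' @param mesh A `legvol_mesh`.
#' @param min_faces Debris threshold (default 100 faces).
#' @return List of `legvol_mesh` components.
#' @export
find_leg_components <- function(mesh, min_faces = 100) {
  comps <- split_mesh_components(mesh)
  comps <- comps[vapply(comps, function(m) nrow(m$faces), 0L) >= min_faces]
  if (length(comps) == 0L) {
    legvol_abort("no components above the debris threshold", "legvol_empty_result")
  }
  comps
}

#' Classify leg visibility from cropped components
#'
#' `"complete"` when the two largest components lie strictly on opposite
#' sides of the median sagittal plane (within tolerance `delta`);
#' `"limited"` when the largest component spans the plane (legs fused in the
#' medial thigh area). A single component that does not span the midline is a
#' single-leg condition and raises an error rather than being silently
#' classified.
#'
#' @param components List of `legvol_mesh`, largest first (from
#'   [find_leg_components()]).
#' @param crop A [crop_config()].
#' @param delta Midline tolerance, mm (default 2, below scanner accuracy, so
#'   touching bounding boxes do not flip the call).
#' @return `"complete"` or `"limited"`.
#' @export
classify_visibility <- function(components, crop, delta = 2) {
  if (length(components) == 0L) legvol_abort("no components", "legvol_empty_result")
  sx <- crop$sagittal_x
  xr <- function(m) range(m$vertices[, 1])
  r1 <- xr(components[[1]])
  if (r1[1] < sx - delta && r1[2] > sx + delta) return("limited")
  if (length(components) >= 2L) {
    r2 <- xr(components[[2]])
    left_first <- r1[1] >= sx - delta && r2[2] <= sx + delta
    right_first <- r1[2] <= sx + delta && r2[1] >= sx - delta
    if (left_first || right_first) return("complete")
  }
  legvol_abort("only one leg found in the crop band (component does not span the midline)",
               "legvol_single_leg")
}

#' Split fused legs at the median sagittal plane
#'
#' Exact clip at `x = sagittal_x`; each half is open along the new planar
#' boundary loops lying in the cut plane. The left half is the subject's left
#' (`x > sagittal_x` in the canonical frame).
#'
#' @param mesh Fused (limited-visibility) cropped `legvol_mesh`.
#' @param sagittal_x Median sagittal plane coordinate, mm.
#' @return List with elements `left` and `right` (`legvol_mesh`).
#' @export
split_sagittal <- function(mesh, sagittal_x = 0) {
  halves <- split_by_plane(mesh, c(1, 0, 0), sagittal_x)
  if (is.null(halves$above) || is.null(halves$below)) {
    legvol_abort("sagittal split leaves one half empty (plane outside the mesh)",
                 "legvol_degenerate_split")
  }
  list(left = halves$above, right = halves$below)
}
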