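# Triangle-mesh data model and structural validation.
#
# A mesh is a pair (vertices, faces): an n x 3 numeric matrix of positions in
# millimetres and an m x 3 integer matrix of 1-based vertex indices. This is
# the universal geometric object of the package; every downstream operation
# (alignment, cropping, repair, volumetry) consumes and produces it.

#' Construct a triangle mesh
#'
#' @param vertices Numeric matrix (or data frame) with 3 columns: x, y, z in
#'   millimetres.
#' @param faces Integer matrix with 3 columns of 1-based vertex indices.
#' @param name Optional mesh name.
#' @param validate Check structural invariants (finite coordinates, indices in
#'   range, no degenerate index triples). Default `TRUE`.
#' @return An object of class `legvol_mesh`.
#' @examples
#' m <- mesh_cube(100)
#' signed_volume(m)  # 1000 mL
#' @export
triangle_mesh <- function(vertices, faces, name = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces, name = name),
                    class = "legvol_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (ncol(v) != 3L) legvol_abort("vertices must have 3 columns", "legvol_domain_error")
  if (nrow(f) > 0 && ncol(f) != 3L) legvol_abort("faces must have 3 columns", "legvol_domain_error")
  if (nrow(v) == 0L || nrow(f) == 0L) {
    legvol_abort("mesh has no vertices or no faces", "legvol_empty_input")
  }
  if (!all(is.finite(v))) legvol_abort("non-finite vertex coordinates", "legvol_domain_error")
  if (min(f) < 1L || max(f) > nrow(v)) {
    legvol_abort("face index out of range", "legvol_domain_error")
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    legvol_abort("face with repeated vertex index", "legvol_domain_error")
  }
  invisible(mesh)
}

#' @export
print.legvol_mesh <- function(x, ...) {
  cat(sprintf("<legvol_mesh%s: %d vertices, %d faces>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# ---- low-level topology helpers -------------------------------------------

# All directed edges, one row per half-edge, in face order:
# rows 1..m are (v1,v2), m+1..2m are (v2,v3), 2m+1..3m are (v3,v1).
directed_edges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

# Undirected edge keys as doubles (exact for < ~9e7 vertices).
edge_keys <- function(edges, nv) {
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  (as.double(lo) - 1) * nv + as.double(hi)
}

directed_keys <- function(edges, nv) {
  (as.double(edges[, 1]) - 1) * nv + as.double(edges[, 2])
}

# Merge vertices closer than `tol` (snap-to-grid welding) and drop faces that
# become degenerate. Grid welding is deterministic and adequate far below the
# scanner resolution scale.
weld_vertices <- function(mesh, tol = 1e-4) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  keep_v <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  good <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[good, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(keep_v))
  remap[used] <- seq_along(used)
  triangle_mesh(keep_v[used, , drop = FALSE], matrix(remap[f], ncol = 3),
                name = mesh$name)
}

# Drop unreferenced vertices.
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$faces], ncol = 3), name = mesh$name)
}

# Boundary loops as lists of vertex index cycles. A boundary half-edge is a
# directed edge whose reverse is absent; on a consistently wound mesh these
# form vertex-disjoint cycles which we walk via a successor map.
boundary_loops <- function(mesh) {
  nv <- nrow(mesh$vertices)
  de <- directed_edges(mesh$faces)
  dk <- directed_keys(de, nv)
  rk <- directed_keys(de[, c(2, 1), drop = FALSE], nv)
  is_boundary <- !(rk %in% dk)
  be <- de[is_boundary, , drop = FALSE]
  if (nrow(be) == 0L) return(list())
  # boundary of face edge (a -> b) is traversed b -> a along the hole rim
  from <- be[, 2]
  to <- be[, 1]
  nxt <- integer(nv)
  nxt[from] <- to
  visited <- logical(nv)
  loops <- list()
  for (s in from) {
    if (visited[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      loop <- c(loop, cur)
      visited[cur] <- TRUE
      cur <- nxt[cur]
      if (cur == s || cur == 0L || visited[cur] && cur != s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# TRUE when every shared edge is used once in each direction and no edge has
# more than two incident faces.
is_consistently_oriented <- function(mesh) {
  nv <- nrow(mesh$vertices)
  de <- directed_edges(mesh$faces)
  dk <- directed_keys(de, nv)
  if (anyDuplicated(dk)) return(FALSE)
  uk <- edge_keys(de, nv)
  !any(table(uk) > 2L)  # no non-manifold edges
}

# Face-adjacency components (edge connectivity): faces are nodes, linked when
# they share an undirected edge.
face_components <- function(mesh) {
  m <- nrow(mesh$faces)
  nv <- nrow(mesh$vertices)
  de <- directed_edges(mesh$faces)
  uk <- edge_keys(de, nv)
  fid <- rep.int(seq_len(m), 3L)
  ord <- order(uk)
  uk <- uk[ord]
  fid <- fid[ord]
  same <- which(uk[-1] == uk[-length(uk)])
  if (length(same) == 0L) return(seq_len(m))
  g <- igraph::graph_from_edgelist(cbind(fid[same], fid[same + 1L]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(m)]
}

# Extract the sub-mesh of a logical/integer face selection.
subset_faces <- function(mesh, sel) {
  compact_mesh(triangle_mesh(mesh$vertices, mesh$faces[sel, , drop = FALSE],
                             name = mesh$name, validate = FALSE))
}

# Split into edge-connected components, descending face count.
split_mesh_components <- function(mesh) {
  comp <- face_components(mesh)
  sizes <- table(comp)
  ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
  lapply(ids, function(i) subset_faces(mesh, comp == i))
}

# Make face windings consistent and, for closed components, outward
# (positive signed volume). Loaded scans are usually already consistent, so
# the common path is a vectorized check plus a per-component sign fix; the
# breadth-first flip propagation only runs on genuinely inconsistent input.
orient_mesh <- function(mesh, fix_sign = TRUE) {
  if (!is_consistently_oriented(mesh)) {
    mesh <- propagate_orientation(mesh)
    if (!is_consistently_oriented(mesh)) {
      legvol_abort("mesh is not orientable (non-manifold edges)", "legvol_format_error")
    }
  }
  if (!fix_sign) return(mesh)
  comp <- face_components(mesh)
  for (i in unique(comp)) {
    sel <- comp == i
    sub <- mesh$faces[sel, , drop = FALSE]
    # only flip closed components; open ones have no well-defined inside
    if (component_closed(mesh, sel) && raw_signed_volume(mesh$vertices, sub) < 0) {
      mesh$faces[sel, ] <- sub[, c(1, 3, 2)]
    }
  }
  mesh
}

component_closed <- function(mesh, sel) {
  nv <- nrow(mesh$vertices)
  de <- directed_edges(mesh$faces[sel, , drop = FALSE])
  dk <- directed_keys(de, nv)
  rk <- directed_keys(de[, c(2, 1), drop = FALSE], nv)
  all(rk %in% dk)
}

# Signed volume in mm^3 of a face set (divergence theorem), no checks.
raw_signed_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

# Greedy breadth-first winding repair for inconsistent meshes.
propagate_orientation <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  nv <- nrow(mesh$vertices)
  de <- directed_edges(f)
  uk <- edge_keys(de, nv)
  fid <- rep.int(seq_len(m), 3L)
  o <- order(uk)
  uk_s <- uk[o]
  fid_s <- fid[o]
  # adjacency: pairs of faces sharing an edge
  same <- which(uk_s[-1] == uk_s[-length(uk_s)])
  adj <- split(c(fid_s[same], fid_s[same + 1L]), c(fid_s[same + 1L], fid_s[same]))
  flipped <- logical(m)
  seen <- logical(m)
  face_dirkeys <- function(i) {
    tri <- f[i, ]
    if (flipped[i]) tri <- tri[c(1, 3, 2)]
    e <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    directed_keys(e, nv)
  }
  for (start in seq_len(m)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      ki <- face_dirkeys(i)
      nb <- adj[[as.character(i)]]
      for (j in nb) {
        if (seen[j]) next
        kj <- face_dirkeys(j)
        # consistent neighbours share the edge in opposite directions
        if (any(kj %in% ki)) flipped[j] <- TRUE
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  if (any(flipped)) f[flipped, ] <- f[flipped, c(1, 3, 2)]
  mesh$faces <- f
  mesh
}

# ---- inspection -------------------------------------------------------------

#' Structural report for a mesh
#'
#' Counts, edge-connected components, boundary loops, watertightness,
#' orientation consistency, and the bounding box. Watertight means: no
#' boundary edges and every edge bordered by exactly two faces.
#'
#' @param mesh A `legvol_mesh`.
#' @return A list of class `legvol_mesh_report` with fields `n_vertices`,
#'   `n_faces`, `n_components`, `boundary_loops` (list of vertex cycles),
#'   `is_watertight`, `is_consistently_oriented`, `bbox` (2x3 min/max matrix).
#' @export
inspect_mesh <- function(mesh) {
  validate_mesh(mesh)
  nv <- nrow(mesh$vertices)
  de <- directed_edges(mesh$faces)
  uk <- edge_keys(de, nv)
  counts <- table(uk)
  loops <- boundary_loops(mesh)
  watertight <- length(loops) == 0L && all(counts == 2L)
  bbox <- rbind(min = apply(mesh$vertices, 2, min),
                max = apply(mesh$vertices, 2, max))
  colnames(bbox) <- c("x", "y", "z")
  structure(list(
    n_vertices = nv,
    n_faces = nrow(mesh$faces),
    n_edges = length(counts),
    n_components = length(unique(face_components(mesh))),
    boundary_loops = loops,
    is_watertight = watertight,
    is_consistently_oriented = is_consistently_oriented(mesh),
    bbox = bbox
  ), class = "legvol_mesh_report")
}

#' @export
print.legvol_mesh_report <- function(x, ...) {
  cat(sprintf(paste0("<mesh report: %d vertices, %d faces, %d component(s), ",
                     "%d boundary loop(s), watertight: %s, oriented: %s>\n"),
              x$n_vertices, x$n_faces, x$n_components,
              length(x$boundary_loops), x$is_watertight,
              x$is_consistently_oriented))
  invisible(x)
}

#' @export
format.legvol_mesh_report <- function(x, ...) {
  jsonlite::toJSON(list(
    n_vertices = x$n_vertices, n_faces = x$n_faces, n_edges = x$n_edges,
    n_components = x$n_components, n_boundary_loops = length(x$boundary_loops),
    is_watertight = x$is_watertight,
    is_consistently_oriented = x$is_consistently_oriented,
    bbox = x$bbox
  ), auto_unbox = TRUE, digits = NA)
}
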