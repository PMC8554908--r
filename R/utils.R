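# Internal helpers: conditions, rigid transforms, seeded RNG.

legvol_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "legvol_error"), ...)
}

`%||%` <- rlang::`%||%`

#' Rigid transform (rotation + translation)
#'
#' A proper rigid motion in millimetre space: `p -> R p + t` with `R`
#' orthonormal, `det(R) = +1`.
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation Numeric 3-vector, millimetres.
#' @return An object of class `legvol_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0) {
    legvol_abort("rotation must be orthonormal with det +1", "legvol_domain_error")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "legvol_rigid")
}

#' @export
print.legvol_rigid <- function(x, ...) {
  cat("<rigid transform>\n")
  m <- cbind(x$rotation, x$translation)
  rownames(m) <- c("x", "y", "z")
  colnames(m) <- c("r1", "r2", "r3", "t")
  print(round(m, 6))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` is the motion "apply `a`, then `b`".
#'
#' @param b,a `legvol_rigid` objects.
#' @return A `legvol_rigid`.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param x A `legvol_rigid`.
#' @return The inverse motion.
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$rotation), as.numeric(-t(x$rotation) %*% x$translation))
}

apply_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, -transform$translation, "-")
}

#' Apply a rigid transform to a mesh
#' @param mesh A `legvol_mesh`.
#' @param transform A `legvol_rigid`.
#' @return The moved mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_points(mesh$vertices, transform)
  mesh
}

#' Rotation matrices about the coordinate axes
#'
#' @param degrees Angle in degrees, right-handed about the named axis.
#' @return A 3x3 rotation matrix.
#' @export
rotation_z <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' @rdname rotation_z
#' @export
rotation_x <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rotation_z
#' @export
rotation_y <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# Rotation taking unit vector `from` onto unit vector `to` (Rodrigues).
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- perp - sum(perp * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

rotation_axis_angle <- function(axis, degrees) {
  axis <- axis / sqrt(sum(axis^2))
  a <- degrees * pi / 180
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(a) * vx + (1 - cos(a)) * vx %*% vx
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
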