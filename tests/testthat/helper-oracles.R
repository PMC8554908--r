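# Independent test oracles, written against the mathematical definitions (not
# against the package implementation).

# Exact volume (mL) of the inscribed N-gon prism produced by mesh_cylinder():
# cross-section area = (1/2) N r^2 sin(2 pi / N).
ngon_prism_volume <- function(radius, height, segments) {
  0.5 * segments * radius^2 * sin(2 * pi / segments) * height / 1000
}

# Brute-force convex hull volume oracle, O(n^4): enumerate all point triples,
# keep those whose plane has every other point on one side (hull facets), and
# sum signed tetrahedron volumes to the centroid with outward-consistent
# facet orientation. Returns mm^3.
hull_volume_oracle <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  total <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c_ <- pts[k, ]
    nrm <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
             (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
             (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sqrt(sum(nrm^2)) < 1e-9) next
    d <- as.numeric(pts %*% nrm) - sum(nrm * a)
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      # facet (points in general position, so each facet is one triple):
      # tetra to the centroid has volume |n . (a - ctr)| / 6 with n the
      # unnormalized facet normal
      total <- total + abs(sum(nrm * (a - ctr))) / 6
    }
  }
  total
}

# Exhaustive two-sided rank-sum p-value and Mann-Whitney W of group a, by full
# enumeration of all labelings (tie-free data only).
rank_sum_oracle <- function(a, b) {
  w_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  w_obs <- w_of(a, b)
  pooled <- c(a, b)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  ws <- apply(combos, 2, function(ix) w_of(pooled[ix], pooled[-ix]))
  n_tot <- ncol(combos)
  mu <- length(a) * length(b) / 2
  p <- sum(abs(ws - mu) >= abs(w_obs - mu) - 1e-12) / n_tot
  list(W = w_obs, p_value = min(1, p))
}

# Numerically integrated leg profile volume (mL), independent of the Simpson
# evaluation in the package.
profile_volume_oracle <- function(profile, z0 = min(profile$z), z1 = max(profile$z)) {
  f <- function(z) {
    a <- stats::approx(profile$z, profile$a, z)$y
    b <- stats::approx(profile$z, profile$b, z)$y
    pi * a * b
  }
  stats::integrate(Vectorize(f), z0, z1, rel.tol = 1e-12)$value / 1000
}

# Small closed test mesh: tetrahedron with volume |det| / 6.
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 40, 0), c(0, 0, 50))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  triangle_mesh(v, f, name = "tetra")
}
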