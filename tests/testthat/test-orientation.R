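make_test_body <- function(fused = FALSE) {
  spec <- if (fused) {
    phantom_spec(stout_leg_profile(), fusion = stout_fusion(), segments = 64)
  } else {
    phantom_spec(slim_leg_profile(), segments = 64)
  }
  make_whole_body_phantom(spec)$mesh
}

test_that("support plane is detected on the turntable to sub-mm accuracy", {
  body <- make_test_body()
  plane <- detect_support_plane(body)
  expect_equal(abs(plane$normal[3]), 1, tolerance = 1e-9)
  expect_equal(plane$offset, 0, tolerance = 1e-6)
  expect_gt(plane$inlier_count, 100)
})

test_that("no-support-plane condition is raised on a sphere", {
  expect_error(detect_support_plane(mesh_uv_sphere(100, 48, 24)),
               class = "legvol_no_support_plane")
})

test_that("random rigid motions are recovered to 0.2 degrees and 0.5 mm", {
  body <- make_test_body()
  set.seed(11)
  worst_ang <- 0
  worst_shift <- 0
  for (rep in 1:20) {
    rot <- rotation_z(runif(1, -180, 180)) %*%
      rotation_x(runif(1, -5, 5)) %*% rotation_y(runif(1, -5, 5))
    tr <- rigid_transform(rot, runif(3, -30, 30))
    o <- orient_scan(transform_mesh(body, tr))
    # composition of recovery after motion should be the identity
    net_rot <- o$transform$rotation %*% tr$rotation
    ang <- acos(pmin(1, (sum(diag(net_rot)) - 1) / 2)) * 180 / pi
    net_shift <- sqrt(sum((o$transform$rotation %*% tr$translation +
                             o$transform$translation)^2))
    worst_ang <- max(worst_ang, ang)
    worst_shift <- max(worst_shift, net_shift)
  }
  expect_lt(worst_ang, 0.2)
  expect_lt(worst_shift, 0.5)
})

test_that("orientation is idempotent and volume-preserving", {
  body <- make_test_body(fused = TRUE)
  v0 <- signed_volume(body)
  o1 <- orient_scan(body)
  o2 <- orient_scan(o1$mesh)
  expect_lt(max(abs(o2$mesh$vertices - o1$mesh$vertices)), 1e-6)
  expect_equal(signed_volume(o1$mesh), v0, tolerance = 1e-9)
})

test_that("frontal facing resolves the anterior direction from the torso", {
  body <- make_test_body()
  turned <- transform_mesh(body, rigid_transform(rotation_z(135)))
  o <- orient_scan(turned)
  v <- o$mesh$vertices
  slab <- v[v[, 3] > 900 & v[, 3] < 1400, , drop = FALSE]
  expect_lt(mean(slab[, 2]), -10)  # torso centroid back at anterior offset
  # torso wider in x than deep in y after facing
  expect_gt(diff(range(slab[, 1])), diff(range(slab[, 2])))
})

test_that("manual facing mode applies the requested angle", {
  body <- make_test_body()
  o <- face_frontal(body, method = "manual", manual_angle = 90)
  expect_equal(o$angle, 90)
  expect_lt(max(abs(o$mesh$vertices -
                      transform_mesh(body, rigid_transform(rotation_z(90)))$vertices)),
            1e-9)
})

test_that("isotropic torso cross-section raises an ambiguity error", {
  # a body whose 'torso' is a circular cylinder has no principal axis
  disc <- legvol:::turntable_disc()
  pr <- data.frame(z = c(100, 1000), a = 100, b = 100)
  tube <- mesh_generalized_cylinder(pr, segments = 48, ring_spacing = 80)
  body <- legvol:::merge_meshes(list(disc, tube))
  expect_error(face_frontal(body), class = "legvol_ambiguous_orientation")
})
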