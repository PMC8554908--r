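test_that("profile volume matches adaptive quadrature", {
  pr <- slim_leg_profile()
  expect_equal(leg_profile_volume(pr), profile_volume_oracle(pr),
               tolerance = 1e-9)
  expect_equal(leg_profile_volume(pr, 70, 810),
               profile_volume_oracle(pr, 70, 810), tolerance = 1e-9)
  # tapered frustum closed form: pi h (r1^2 + r1 r2 + r2^2) / 3
  taper <- data.frame(z = c(0, 400), a = c(60, 40), b = c(60, 40))
  expect_equal(leg_profile_volume(taper),
               pi * 400 * (60^2 + 60 * 40 + 40^2) / 3 / 1000,
               tolerance = 1e-12)
})

test_that("profile validation rejects malformed knot tables", {
  expect_error(phantom_spec(data.frame(z = c(0, 0), a = 1, b = 1)),
               class = "legvol_spec_error")
  expect_error(phantom_spec(data.frame(z = c(0, 1), a = c(1, -1), b = 1)),
               class = "legvol_spec_error")
})

test_that("single leg phantoms are watertight with near-analytic volume", {
  spec <- phantom_spec(slim_leg_profile(), segments = 256)
  leg <- make_leg_phantom(spec, "left")
  rep <- inspect_mesh(leg$mesh)
  expect_true(rep$is_watertight)
  expect_equal(rep$n_vertices - rep$n_edges + rep$n_faces, 2)
  err <- abs(signed_volume(leg$mesh) - leg$analytic_volume) / leg$analytic_volume
  expect_lt(err, 0.005)
  right <- make_leg_phantom(spec, "right")$mesh
  expect_lt(max(right$vertices[, 1]), 0)
  expect_gt(min(leg$mesh$vertices[, 1]), 0)
})

test_that("discretisation error decreases quadratically with segment count", {
  pr <- data.frame(z = c(0, 400), a = c(60, 40), b = c(60, 40))
  truth <- leg_profile_volume(pr)
  err <- vapply(c(32, 64, 128), function(n) {
    abs(signed_volume(mesh_generalized_cylinder(pr, segments = n)) - truth)
  }, 0)
  # quadratic convergence: each doubling divides the error by ~4
  expect_gt(err[1] / err[2], 3.5)
  expect_lt(err[1] / err[2], 4.5)
  expect_gt(err[2] / err[3], 3.5)
  expect_lt(err[2] / err[3], 4.5)
})

test_that("ring spacing does not change the enclosed volume (ruled surface)", {
  pr <- slim_leg_profile()
  v1 <- signed_volume(mesh_generalized_cylinder(pr, segments = 64, ring_spacing = 10))
  v2 <- signed_volume(mesh_generalized_cylinder(pr, segments = 64, ring_spacing = 200))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("medial lean preserves slice areas and hence the volume", {
  pr <- slim_leg_profile()
  straight <- pr; straight$cx <- 120
  v_lean <- signed_volume(mesh_generalized_cylinder(pr, segments = 64))
  v_straight <- signed_volume(mesh_generalized_cylinder(straight, segments = 64))
  expect_equal(v_lean, v_straight, tolerance = 1e-9)
})

test_that("fused pair is one watertight component matching its closed form", {
  spec <- phantom_spec(stout_leg_profile(), fusion = stout_fusion(), segments = 128)
  fp <- make_fused_pair(spec)
  rep <- inspect_mesh(fp$mesh)
  expect_true(rep$is_watertight)
  expect_true(rep$is_consistently_oriented)
  expect_equal(rep$n_components, 1L)
  v <- signed_volume(fp$mesh)
  expect_lt(abs(v - fp$total_truth) / fp$total_truth, 0.005)
  expect_equal(fp$left_truth + fp$right_truth, fp$total_truth, tolerance = 1e-12)
})

test_that("bridge cross-section area matches a dense polygonal oracle", {
  r <- 95; c_off <- 100; w <- 36
  # dense shoelace of the union outline: two circle arcs + two segments
  th0 <- asin(w / r)
  t_right <- seq(th0, 2 * pi - th0, length.out = 20001)
  t_left <- seq(pi + th0, pi - th0 + 2 * pi, length.out = 20001)
  poly <- rbind(cbind(-c_off + r * cos(t_right), r * sin(t_right)),
                cbind(c_off + r * cos(t_left), r * sin(t_left)))
  n <- nrow(poly)
  area <- abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
                    poly[c(2:n, 1), 1] * poly[, 2])) / 2
  extra_oracle <- area - 2 * pi * r^2
  expect_equal(legvol:::bridge_extra_area(r, c_off, w), extra_oracle,
               tolerance = 1e-5)
})

test_that("fusion requires a circular constant band and even segments", {
  pr <- stout_leg_profile()
  pr$b[4] <- 80  # elliptical in the band
  expect_error(make_fused_pair(phantom_spec(pr, fusion = stout_fusion())),
               class = "legvol_spec_error")
  expect_error(make_fused_pair(phantom_spec(stout_leg_profile(),
                                            fusion = stout_fusion(),
                                            segments = 127)),
               class = "legvol_spec_error")
  expect_error(make_fused_pair(phantom_spec(stout_leg_profile())),
               class = "legvol_spec_error")
})

test_that("whole-body phantom has disc, legs and torso and a recorded motion", {
  spec <- phantom_spec(slim_leg_profile(), segments = 48)
  tr <- rigid_transform(rotation_z(25), c(10, 5, 2))
  body <- make_whole_body_phantom(spec, transform = tr)
  expect_equal(inspect_mesh(body$mesh)$n_components, 4L)  # disc + 2 legs + torso
  expect_identical(body$transform, tr)
  expect_equal(nrow(body$truth), 2)
})

test_that("perturbation is seed-deterministic and identity at zero noise", {
  m <- mesh_cube(100)
  n <- noise_spec()
  expect_identical(perturb_scan(m, n, seed = 5)$vertices,
                   perturb_scan(m, n, seed = 5)$vertices)
  expect_false(identical(perturb_scan(m, n, seed = 5)$vertices,
                         perturb_scan(m, n, seed = 6)$vertices))
  expect_identical(perturb_scan(m, noise_spec(0, 0, 0)), m)
  expect_error(perturb_scan(m, n), class = "legvol_domain_error")
  # perturbation must not disturb the global RNG stream
  set.seed(1); before <- stats::rnorm(1)
  set.seed(1); invisible(perturb_scan(m, n, seed = 9)); after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("simulated study is reproducible and carries analytic truth", {
  s1 <- simulate_precision_study(n_subjects = 3, seed = 4, segments = 48)
  s2 <- simulate_precision_study(n_subjects = 3, seed = 4, segments = 48)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$scans[[2]][[1]]$vertices, s2$scans[[2]][[1]]$vertices)
  expect_equal(nrow(s1$truth), 6)
  expect_identical(s1$subjects$variant,
                   ifelse(s1$subjects$bmi >= 30, "limited", "complete"))
  expect_true(all(s1$truth$truth_ml >= s1$truth$twin_ml))
})
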