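test_that("crop_config validates its planes", {
  expect_s3_class(crop_config(70, 810), "legvol_crop")
  expect_error(crop_config(810, 70), class = "legvol_domain_error")
  expect_error(crop_config(-5, 810), class = "legvol_domain_error")
})

test_that("transverse crop keeps exactly the band and is exact at the planes", {
  cyl <- mesh_cylinder(50, 400, segments = 128)
  band <- crop_transverse(cyl, crop_config(100, 300))
  zr <- range(band$vertices[, 3])
  expect_equal(zr, c(100, 300), tolerance = 1e-9)
  capped <- fill_holes_flat(band)
  expect_equal(signed_volume(capped), ngon_prism_volume(50, 200, 128),
               tolerance = 1e-9)
})

test_that("empty crop band raises an empty-result error", {
  cyl <- mesh_cylinder(50, 400)
  expect_error(crop_transverse(cyl, crop_config(1000, 1200)),
               class = "legvol_empty_result")
})

test_that("plane split is exactly volume-additive after capping", {
  spec <- phantom_spec(stout_leg_profile(), fusion = stout_fusion(), segments = 64)
  fused <- make_fused_pair(spec)$mesh
  total <- signed_volume(fused)
  for (off in c(-3.7, 0, 5.2)) {
    halves <- legvol:::split_by_plane(fused, c(1, 0, 0), off)
    va <- signed_volume(fill_holes_flat(halves$above))
    vb <- signed_volume(fill_holes_flat(halves$below))
    expect_lt(abs(va + vb - total), 1e-6)
  }
  # transverse planes, including one through the fusion band
  for (z in c(200, 700)) {
    halves <- legvol:::split_by_plane(fused, c(0, 0, 1), z)
    va <- signed_volume(fill_holes_flat(halves$above))
    vb <- signed_volume(fill_holes_flat(halves$below))
    expect_lt(abs(va + vb - total), 1e-6)
  }
})

test_that("debris below the face threshold is discarded", {
  leg <- make_leg_phantom(phantom_spec(slim_leg_profile(), segments = 64), "left")$mesh
  debris <- mesh_cube(2, center = c(300, 300, 100))  # 12 faces
  merged <- legvol:::merge_meshes(list(leg, debris))
  comps <- find_leg_components(merged, min_faces = 100)
  expect_length(comps, 1)
  expect_error(find_leg_components(debris, min_faces = 100),
               class = "legvol_empty_result")
})

test_that("visibility classification separates complete, limited and single-leg", {
  crop <- crop_config(70, 810)
  left <- make_leg_phantom(phantom_spec(slim_leg_profile(), segments = 48), "left")$mesh
  right <- make_leg_phantom(phantom_spec(slim_leg_profile(), segments = 48), "right")$mesh
  expect_equal(classify_visibility(list(left, right), crop), "complete")
  fused <- make_fused_pair(phantom_spec(stout_leg_profile(),
                                        fusion = stout_fusion(), segments = 64))$mesh
  expect_equal(classify_visibility(list(fused), crop), "limited")
  expect_error(classify_visibility(list(left), crop), class = "legvol_single_leg")
})

test_that("sagittal split yields left and right halves, errors when degenerate", {
  fused <- make_fused_pair(phantom_spec(stout_leg_profile(),
                                        fusion = stout_fusion(), segments = 64))$mesh
  halves <- split_sagittal(fused, 0)
  expect_gt(min(halves$left$vertices[, 1]), -1e-9)
  expect_lt(max(halves$right$vertices[, 1]), 1e-9)
  expect_error(split_sagittal(fused, 10000), class = "legvol_degenerate_split")
})
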