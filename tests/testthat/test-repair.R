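test_that("flat fill closes a half cylinder exactly at the rectangular cut", {
  cyl <- mesh_cylinder(50, 400, segments = 128)
  v_full <- signed_volume(cyl)
  half <- legvol:::split_by_plane(cyl, c(1, 0, 0), 0)$above
  filled <- fill_holes_flat(half)
  expect_true(inspect_mesh(filled)$is_watertight)
  # the planar cut contributes no volume, so the half is exactly half
  expect_equal(signed_volume(filled), v_full / 2, tolerance = 1e-12)
})

test_that("flat fill skips loops lying in the supplied planes", {
  band <- crop_transverse(mesh_cylinder(50, 400, segments = 64),
                          crop_config(100, 300))
  planes <- list(legvol:::plane_spec(c(0, 0, 1), 100),
                 legvol:::plane_spec(c(0, 0, 1), 300))
  out <- fill_holes_flat(band, skip_planes = planes)
  expect_length(boundary_loops(out), 2)
  capped <- cap_planar_boundaries(out, planes)
  expect_true(inspect_mesh(capped)$is_watertight)
})

test_that("small holes are re-closed with negligible volume change", {
  m <- mesh_uv_sphere(50, 48, 24)
  v0 <- signed_volume(m)
  holed <- inject_hole(m, c(50, 0, 0), 12)
  expect_gt(length(boundary_loops(holed)), 0)
  fixed <- fill_small_holes(holed)
  expect_true(inspect_mesh(fixed)$is_watertight)
  expect_lt(abs(signed_volume(fixed) - v0) / v0, 0.005)
})

test_that("large holes are left for explicit handling", {
  m <- mesh_uv_sphere(50, 48, 24)
  holed <- inject_hole(m, c(50, 0, 0), 30)
  out <- fill_small_holes(holed, repair_params(small_hole_max_edges = 10))
  expect_gt(length(boundary_loops(out)), 0)
})

test_that("spike removal excises an artificial spike and spares clean meshes", {
  m <- mesh_uv_sphere(50, 24, 12)
  clean <- remove_spikes(m)
  expect_identical(attr(clean, "spikes_removed"), 0L)
  expect_identical(clean$faces, m$faces)
  spiked <- m
  vi <- which.max(spiked$vertices[, 3])
  spiked$vertices[vi, ] <- spiked$vertices[vi, ] * 3  # yank one vertex outward
  out <- remove_spikes(spiked)
  expect_gt(attr(out, "spikes_removed"), 0)
  expect_true(inspect_mesh(out)$is_watertight)
  expect_equal(signed_volume(out), signed_volume(m), tolerance = 0.01)
})

test_that("spike removal tolerates anisotropic but regular meshing", {
  # tall thin wall quads (40 mm rings vs ~2.5 mm angular step) must not be
  # flagged; nor the sharp 90-degree rim between wall and flat cap
  pr <- data.frame(z = c(0, 400), a = 25, b = 25)
  m <- mesh_generalized_cylinder(pr, segments = 64, ring_spacing = 40)
  out <- remove_spikes(m)
  expect_identical(attr(out, "spikes_removed"), 0L)
})

test_that("ear clipping triangulates concave and collinear polygons", {
  # L-shape (concave)
  L <- rbind(c(0, 0), c(4, 0), c(4, 1), c(1, 1), c(1, 3), c(0, 3))
  tris <- legvol:::ear_clip(L)
  expect_equal(nrow(tris), nrow(L) - 2)
  area <- function(p, tr) sum(apply(tr, 1, function(t_) {
    a <- p[t_[1], ]; b <- p[t_[2], ]; c_ <- p[t_[3], ]
    ((b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])) / 2
  }))
  expect_equal(area(L, tris), 4 + 2, tolerance = 1e-12)
  # square with collinear midpoints on every edge
  sq <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2), c(1, 2),
              c(0, 2), c(0, 1))
  tris2 <- legvol:::ear_clip(sq)
  expect_equal(nrow(tris2), nrow(sq) - 2)
  expect_equal(area(sq, tris2), 4, tolerance = 1e-12)
})

test_that("repair_segment produces a watertight oriented mesh; failures are typed", {
  crop <- crop_config(70, 810)
  spec <- phantom_spec(stout_leg_profile(), fusion = stout_fusion(), segments = 64)
  body <- make_whole_body_phantom(spec)$mesh
  band <- crop_transverse(body, crop)
  comps <- find_leg_components(band)
  halves <- split_sagittal(comps[[1]], 0)
  seg <- repair_segment(halves$left, crop)
  rep <- inspect_mesh(seg)
  expect_true(rep$is_watertight)
  expect_true(rep$is_consistently_oriented)
  expect_error(signed_volume(halves$left), class = "legvol_open_mesh_error")
})
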