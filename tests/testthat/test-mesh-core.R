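test_that("triangle_mesh validates structure and reports errors by class", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(triangle_mesh(v, rbind(c(1, 2, 3))), "legvol_mesh")
  expect_error(triangle_mesh(v[0, , drop = FALSE], matrix(0L, 0, 3)),
               class = "legvol_empty_input")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), class = "legvol_domain_error")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), class = "legvol_domain_error")
  v_bad <- v; v_bad[1, 1] <- NaN
  expect_error(triangle_mesh(v_bad, rbind(c(1, 2, 3))), class = "legvol_domain_error")
})

test_that("closed primitives satisfy the Euler characteristic V - E + F = 2", {
  for (m in list(mesh_cube(10), tetra_mesh(), mesh_uv_sphere(5, 16, 8),
                 mesh_cylinder(5, 20, segments = 32))) {
    rep <- inspect_mesh(m)
    expect_equal(rep$n_vertices - rep$n_edges + rep$n_faces, 2)
    expect_true(rep$is_watertight)
    expect_true(rep$is_consistently_oriented)
    expect_equal(rep$n_components, 1L)
  }
})

test_that("weld_vertices merges coincident vertices and preserves volume", {
  m <- mesh_cube(50)
  # duplicate every vertex so each face uses its own copies
  f <- m$faces
  v_dup <- m$vertices[as.vector(t(f)), , drop = FALSE]
  f_dup <- matrix(seq_len(nrow(v_dup)), ncol = 3, byrow = TRUE)
  soup <- triangle_mesh(v_dup, f_dup)
  expect_gt(length(boundary_loops(soup)), 0)
  welded <- weld_vertices(soup)
  expect_equal(nrow(welded$vertices), 8)
  expect_equal(signed_volume(welded), 125, tolerance = 1e-12)
  expect_true(inspect_mesh(welded)$is_watertight)
})

test_that("boundary_loops finds the rim of a punctured cube", {
  m <- mesh_cube(10)
  open <- subset_faces(m, seq_len(nrow(m$faces)) != 1L)
  loops <- boundary_loops(open)
  expect_length(loops, 1)
  expect_length(loops[[1]], 3)
  expect_false(inspect_mesh(open)$is_watertight)
})

test_that("orient_mesh repairs scrambled windings and inward orientation", {
  m <- mesh_uv_sphere(20, 24, 12)
  v_true <- signed_volume(m)
  scr <- m
  set.seed(42)
  flip <- sample(nrow(scr$faces), nrow(scr$faces) %/% 3)
  scr$faces[flip, ] <- scr$faces[flip, c(1, 3, 2)]
  expect_false(inspect_mesh(scr)$is_consistently_oriented)
  fixed <- orient_mesh(scr)
  expect_true(inspect_mesh(fixed)$is_consistently_oriented)
  expect_equal(signed_volume(fixed), v_true, tolerance = 1e-12)
  # fully inverted mesh: consistent but inward; sign fix restores outward
  inv <- m
  inv$faces <- inv$faces[, c(1, 3, 2)]
  expect_equal(signed_volume(orient_mesh(inv)), v_true, tolerance = 1e-12)
  # idempotence
  expect_identical(orient_mesh(fixed)$faces, fixed$faces)
})

test_that("split_mesh_components separates disjoint solids by size", {
  a <- mesh_cube(10)
  b <- mesh_cube(5, center = c(100, 0, 0))
  b2 <- mesh_uv_sphere(8, 24, 12)
  b2$vertices[, 2] <- b2$vertices[, 2] + 200
  merged <- triangle_mesh(
    rbind(a$vertices, b$vertices, b2$vertices),
    rbind(a$faces, b$faces + nrow(a$vertices),
          b2$faces + nrow(a$vertices) + nrow(b$vertices)))
  comps <- split_mesh_components(merged)
  expect_length(comps, 3)
  nf <- vapply(comps, function(m) nrow(m$faces), 0L)
  expect_true(all(diff(nf) <= 0))  # descending size
  expect_equal(sum(nf), nrow(merged$faces))
})

test_that("inspect_mesh report prints and serialises", {
  rep <- inspect_mesh(mesh_cube(10))
  expect_output(print(rep), "watertight")
  expect_match(format(rep), "\"n_faces\"")
})
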