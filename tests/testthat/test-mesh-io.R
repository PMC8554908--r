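sorted_vertices <- function(m) {
  v <- m$vertices
  v[order(round(v[, 1], 4), round(v[, 2], 4), round(v[, 3], 4)), ]
}

test_that("write/read round-trips preserve geometry in every format", {
  m <- mesh_uv_sphere(30, 24, 12)
  v0 <- signed_volume(m)
  tols <- c(stl = 1e-5, stl_ascii = 1e-6, ply = 1e-9, ply_binary = 1e-5,
            obj = 1e-9)
  for (fmt in names(tols)) {
    path <- withr::local_tempfile(fileext = paste0(".", sub("_.*", "", fmt)))
    write_mesh(m, path, format = fmt)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$vertices), nrow(m$vertices), info = fmt)
    expect_equal(nrow(m2$faces), nrow(m$faces), info = fmt)
    expect_lt(max(abs(sorted_vertices(m2) - sorted_vertices(m))),
              tols[[fmt]] * 30 + 1e-12)
    expect_equal(signed_volume(m2), v0, tolerance = tols[[fmt]])
  }
})

test_that("format is inferred from the file extension", {
  m <- mesh_cube(10)
  for (ext in c("stl", "ply", "obj")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    expect_equal(signed_volume(read_mesh(path)), 1, tolerance = 1e-5)
  }
  expect_error(write_mesh(m, withr::local_tempfile(fileext = ".xyz")),
               class = "legvol_format_error")
})

test_that("IO failures raise typed errors", {
  expect_error(read_mesh(file.path(tempdir(), "does_not_exist.stl")),
               class = "legvol_io_error")
  empty <- withr::local_tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_mesh(empty), class = "legvol_empty_input")
})

test_that("truncated binary STL reports the byte offset", {
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(mesh_cube(10), path, format = "stl")
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[1:(length(full) - 30)], path)
  expect_error(read_mesh(path), "byte offset", class = "legvol_format_error")
})

test_that("malformed PLY and OBJ raise format errors", {
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not a ply", "junk"), p)
  expect_error(read_mesh(p), class = "legvol_format_error")
  o <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3 1"), o)
  expect_error(read_mesh(o), class = "legvol_format_error")
})

test_that("OBJ faces with texture/normal slashes parse", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 10 0 0", "v 0 10 0", "v 0 0 10",
               "f 1/1 3/2/2 2/3", "f 1//1 2 4", "f 2 3 4", "f 1 4 3"), p)
  m <- read_mesh(p)
  expect_equal(nrow(m$faces), 4)
  expect_true(inspect_mesh(m)$is_watertight)
})

test_that("unit scaling applies on read", {
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh_cube(1), p)  # a 1 mm cube, e.g. metres stored by mistake
  m <- read_mesh(p, scale = 1000)
  expect_equal(signed_volume(m), 1e6, tolerance = 1e-9)  # now a 1 m cube in mm
})

test_that("read_mesh welds duplicated vertices from face-soup STL", {
  # binary STL stores one vertex record per face corner; reading must weld
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(mesh_cube(20), path, format = "stl")
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 8)
  expect_true(inspect_mesh(m)$is_watertight)
})
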