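# Mesh file input/output: STL (binary + ASCII), PLY (ASCII + binary little
# endian), OBJ (v/f records). Coordinates are interpreted as millimetres;
# STL and OBJ carry no units, so a global scale can be applied on read.

#' Read a triangle mesh
#'
#' Reads STL (binary or ASCII), PLY (ASCII or binary little-endian) or OBJ.
#' Duplicate vertices within `weld_tol` are merged, windings are made
#' consistent, and closed components are oriented outward (volume computation
#' requires consistent outward normals, so orientation is repaired on load,
#' not assumed).
#'
#' @param path File path.
#' @param format One of `"stl"`, `"ply"`, `"obj"`, `"auto"` (by extension).
#' @param scale Global scale applied to coordinates; defaults to
#'   `getOption("legvol.scale", 1)`. Use e.g. `1000` for meshes saved in
#'   metres.
#' @param weld_tol Vertex weld tolerance in mm (default 1e-4, far below the
#'   ~1 mm resolution of surface scanners).
#' @return A `legvol_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      scale = getOption("legvol.scale", 1),
                      weld_tol = 1e-4) {
  format <- match.arg(format)
  if (!file.exists(path)) legvol_abort(paste0("file not found: ", path), "legvol_io_error")
  if (file.size(path) == 0) {
    legvol_abort(paste0("empty file (0 bytes): ", path), "legvol_empty_input")
  }
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj")) {
      legvol_abort(paste0("cannot infer mesh format from extension: ", path),
                   "legvol_format_error")
    }
  }
  raw_mesh <- switch(format,
                     stl = read_stl(path),
                     ply = read_ply(path),
                     obj = read_obj(path))
  if (nrow(raw_mesh$vertices) == 0L || nrow(raw_mesh$faces) == 0L) {
    legvol_abort(paste0("mesh contains no geometry: ", path), "legvol_empty_input")
  }
  if (scale != 1) raw_mesh$vertices <- raw_mesh$vertices * scale
  mesh <- weld_vertices(triangle_mesh(raw_mesh$vertices, raw_mesh$faces,
                                      name = raw_mesh$name), tol = weld_tol)
  orient_mesh(mesh)
}

#' Write a triangle mesh
#'
#' @param mesh A valid `legvol_mesh`.
#' @param path Output path.
#' @param format `"stl"` (binary), `"stl_ascii"`, `"ply"` (ASCII, double
#'   precision), `"ply_binary"` (little-endian doubles), `"obj"`, or
#'   `"auto"` by extension (binary STL, ASCII PLY).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl", "stl_ascii", "ply", "ply_binary", "obj")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", ply = "ply", obj = "obj",
                     legvol_abort("cannot infer format from extension", "legvol_format_error"))
  }
  switch(format,
         stl = write_stl_binary(mesh, path),
         stl_ascii = write_stl_ascii(mesh, path),
         ply = write_ply_ascii(mesh, path),
         ply_binary = write_ply_binary(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

# ---- STL --------------------------------------------------------------------

read_stl <- function(path) {
  n_bytes <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = min(84, n_bytes))
  if (length(header) >= 84) {
    nf <- readBin(header[81:84], "integer", size = 4, endian = "little")
    if (n_bytes == 84 + 50 * as.double(nf)) {
      return(read_stl_binary_body(con, nf, path))
    }
  }
  # not a well-formed binary STL; try ASCII
  txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (is.null(txt) || !grepl("^\\s*solid", txt[1])) {
    legvol_abort(sprintf(
      "not a valid STL: binary face count inconsistent with size %d bytes and no ASCII 'solid' header (byte offset 0)",
      n_bytes), "legvol_format_error")
  }
  read_stl_ascii_text(txt, path)
}

read_stl_binary_body <- function(con, nf, path) {
  body <- readBin(con, "raw", n = 50 * nf)
  if (length(body) < 50 * nf) {
    legvol_abort(sprintf("truncated binary STL '%s' at byte offset %d (expected %d data bytes)",
                         path, 84 + length(body), 50 * nf), "legvol_format_error")
  }
  # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute
  sel <- as.vector(outer(1:48, seq(0L, 50L * (nf - 1L), by = 50L), "+"))
  vals <- readBin(body[sel], "numeric", size = 4, n = 12 * nf, endian = "little")
  rec <- matrix(vals, nrow = 12)  # columns are faces
  verts <- rbind(t(rec[4:6, , drop = FALSE]),
                 t(rec[7:9, , drop = FALSE]),
                 t(rec[10:12, , drop = FALSE]))
  # interleave back to per-face order
  idx <- as.vector(t(matrix(seq_len(3 * nf), nrow = nf)))
  verts <- verts[idx, , drop = FALSE]
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces, name = NULL)
}

read_stl_ascii_text <- function(txt, path) {
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3 != 0L) {
    legvol_abort(sprintf("malformed ASCII STL '%s': %d vertex records (byte offset unknown, not a multiple of 3)",
                         path, length(vlines)), "legvol_format_error")
  }
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE)
  if (length(nums) != 3 * length(vlines)) {
    legvol_abort(sprintf("malformed ASCII STL '%s': non-numeric vertex data", path),
                 "legvol_format_error")
  }
  verts <- matrix(nums, ncol = 3, byrow = TRUE)
  name <- sub("^\\s*solid\\s*", "", txt[1])
  if (name == "") name <- NULL
  list(vertices = verts,
       faces = matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE),
       name = name)
}

write_stl_binary <- function(mesh, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    legvol_abort(paste0("cannot open for writing: ", path), "legvol_io_error"))
  on.exit(close(con))
  nf <- nrow(mesh$faces)
  header <- raw(80)
  label <- charToRaw(sprintf("legvol binary STL%s",
                             if (is.null(mesh$name)) "" else paste0(": ", mesh$name)))
  header[seq_len(min(80, length(label)))] <- label[seq_len(min(80, length(label)))]
  writeBin(header, con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)
  rec <- t(cbind(n, a, b, c_))  # 12 floats per face, column per face
  fbytes <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
  fmat <- matrix(fbytes, nrow = 48)
  out <- matrix(as.raw(0), nrow = 50, ncol = nf)
  out[1:48, ] <- fmat
  writeBin(as.vector(out), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  vfmt <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c(paste0("solid ", mesh$name %||% "legvol"),
             as.vector(rbind("  facet normal 0 0 0",
                             "    outer loop",
                             vfmt(a), vfmt(b), vfmt(c_),
                             "    endloop",
                             "  endfacet")),
             paste0("endsolid ", mesh$name %||% "legvol"))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) legvol_abort(paste0("cannot write: ", path), "legvol_io_error")
  invisible(path)
}

# ---- PLY --------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) legvol_abort(sprintf("truncated PLY header in '%s'", path),
                                        "legvol_format_error")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 200) legvol_abort("PLY header too long", "legvol_format_error")
  }
  if (trimws(header[1]) != "ply") {
    legvol_abort(sprintf("'%s' is not a PLY file (byte offset 0)", path), "legvol_format_error")
  }
  fmt_line <- grep("^format ", trimws(header), value = TRUE)
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) legvol_abort("PLY header lacks vertex/face counts",
                                           "legvol_format_error")
  # vertex property layout (we require the first three to be x, y, z)
  helems <- trimws(header)
  vstart <- grep("^element vertex", helems)
  vprops <- character(0); vtypes <- character(0)
  for (i in seq(vstart + 1L, length(helems))) {
    if (!grepl("^property ", helems[i])) break
    parts <- strsplit(helems[i], "\\s+")[[1]]
    if (parts[2] == "list") break
    vtypes <- c(vtypes, parts[2]); vprops <- c(vprops, parts[3])
  }
  if (length(vprops) < 3 || !identical(vprops[1:3], c("x", "y", "z"))) {
    legvol_abort("PLY vertex element must begin with x, y, z properties",
                 "legvol_format_error")
  }
  if (fmt == "ascii") {
    read_ply_ascii_body(path, length(header), nv, nf, length(vprops))
  } else if (fmt == "binary_little_endian") {
    read_ply_binary_body(con, nv, nf, vtypes, path)
  } else {
    legvol_abort(paste0("unsupported PLY format: ", fmt), "legvol_format_error")
  }
}

read_ply_ascii_body <- function(path, header_len, nv, nf, n_vprops) {
  txt <- readLines(path, warn = FALSE)
  body <- txt[-seq_len(header_len)]
  if (length(body) < nv + nf) {
    legvol_abort(sprintf("truncated ASCII PLY '%s': %d body lines, expected %d",
                         path, length(body), nv + nf), "legvol_format_error")
  }
  vnums <- scan(text = body[seq_len(nv)], quiet = TRUE)
  verts <- matrix(vnums, ncol = n_vprops, byrow = TRUE)[, 1:3, drop = FALSE]
  fnums <- scan(text = body[nv + seq_len(nf)], quiet = TRUE)
  fmat <- matrix(fnums, nrow = nf, byrow = TRUE)
  if (any(fmat[, 1] != 3)) legvol_abort("PLY contains non-triangle faces",
                                        "legvol_format_error")
  list(vertices = verts, faces = fmat[, 2:4, drop = FALSE] + 1L, name = NULL)
}

read_ply_binary_body <- function(con, nv, nf, vtypes, path) {
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  sz <- sizes[vtypes]
  if (any(is.na(sz))) legvol_abort("unsupported PLY vertex property type",
                                   "legvol_format_error")
  vrec <- sum(sz)
  vraw <- readBin(con, "raw", n = vrec * nv)
  if (length(vraw) < vrec * nv) {
    legvol_abort(sprintf("truncated binary PLY '%s' in vertex data at byte offset %d",
                         path, length(vraw)), "legvol_format_error")
  }
  offs <- cumsum(c(0L, sz))[1:3]
  verts <- vapply(1:3, function(k) {
    sel <- as.vector(outer(seq_len(sz[k]), offs[k] + seq(0L, vrec * (nv - 1L), by = vrec), "+"))
    readBin(vraw[sel], "numeric", size = sz[k], n = nv, endian = "little")
  }, numeric(nv))
  frec <- 1L + 3L * 4L  # uchar count + 3 int32
  fraw <- readBin(con, "raw", n = frec * nf)
  if (length(fraw) < frec * nf) {
    legvol_abort(sprintf("truncated binary PLY '%s' in face data at byte offset %d",
                         path, vrec * nv + length(fraw)), "legvol_format_error")
  }
  counts <- as.integer(fraw[seq(1L, by = frec, length.out = nf)])
  if (any(counts != 3L)) legvol_abort("PLY contains non-triangle faces",
                                      "legvol_format_error")
  sel <- as.vector(outer(2:13, seq(0L, frec * (nf - 1L), by = frec), "+"))
  idx <- readBin(fraw[sel], "integer", size = 4, n = 3 * nf, endian = "little")
  faces <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
  list(vertices = matrix(verts, ncol = 3), faces = faces, name = NULL)
}

ply_header_lines <- function(mesh, fmt) {
  c("ply",
    paste("format", fmt, "1.0"),
    "comment produced by legvol",
    paste("element vertex", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header")
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  lines <- c(ply_header_lines(mesh, "ascii"),
             sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) legvol_abort(paste0("cannot write: ", path), "legvol_io_error")
  invisible(path)
}

write_ply_binary <- function(mesh, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    legvol_abort(paste0("cannot open for writing: ", path), "legvol_io_error"))
  on.exit(close(con))
  writeLines(ply_header_lines(mesh, "binary_little_endian"), con)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
  f <- mesh$faces - 1L
  nf <- nrow(f)
  fbytes <- writeBin(as.integer(t(f)), raw(), size = 4, endian = "little")
  out <- matrix(as.raw(0), nrow = 13, ncol = nf)
  out[1, ] <- as.raw(3)
  out[2:13, ] <- matrix(fbytes, nrow = 12)
  writeBin(as.vector(out), con)
  invisible(path)
}

# ---- OBJ --------------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L) {
    legvol_abort(sprintf("'%s' has no v/f records", path), "legvol_format_error")
  }
  vnums <- scan(text = sub("^v\\s+", "", vlines), quiet = TRUE)
  verts <- matrix(vnums, ncol = 3, byrow = TRUE)
  ftok <- strsplit(trimws(sub("^f\\s+", "", flines)), "\\s+")
  if (any(lengths(ftok) != 3L)) {
    legvol_abort(sprintf("'%s' contains non-triangle faces", path), "legvol_format_error")
  }
  idx <- suppressWarnings(as.integer(sub("/.*$", "", unlist(ftok))))
  if (any(is.na(idx)) || any(idx < 1L)) {
    legvol_abort(sprintf("'%s': unsupported or negative face indices", path),
                 "legvol_format_error")
  }
  list(vertices = verts, faces = matrix(idx, ncol = 3, byrow = TRUE), name = NULL)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c(paste0("# legvol OBJ export", if (!is.null(mesh$name)) paste0(": ", mesh$name) else ""),
             sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) legvol_abort(paste0("cannot write: ", path), "legvol_io_error")
  invisible(path)
}
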