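#' Read an STL surface mesh
#'
#' Reads ASCII or binary STL. The dialect is auto-detected: a file whose
#' first bytes read `solid` is probed for ASCII `facet` records before
#' falling back to binary (binary files written by some exporters also
#' begin with `solid`). STL stores each facet independently, so vertices
#' shared between facets are merged on read (coordinates identical within
#' 1e-6 mm); exactly duplicated facets are dropped. Coordinates are
#' interpreted as millimetres.
#'
#' @param path path to an `.stl` file.
#' @param frame the [anatomical_frame()] to attach; STL itself carries no
#'   axis information.
#' @return A [triangle_mesh()].
#' @examples
#' m <- generate_surface(endplate_spec(depth_sagittal = 2, resolution = 16))
#' f <- tempfile(fileext = ".stl")
#' write_stl(m, f)
#' m2 <- read_stl(f)
#' nrow(m2$faces) == nrow(m$faces)
#' @export
read_stl <- function(path, frame = anatomical_frame()) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "epmorph_io_error")
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = 1024L)
  close(con)
  if (length(head_raw) == 0) {
    stopf("empty STL file: %s", path, class = "epmorph_empty_error")
  }
  # byte-level probe: binary headers may be arbitrary bytes
  starts_solid <- length(grepRaw("^[ \t\r\n]*solid", head_raw)) > 0
  has_facet <- length(grepRaw("facet", head_raw, fixed = TRUE)) > 0
  is_ascii <- starts_solid && has_facet
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0) stopf("STL file contains no facets: %s", path,
                            class = "epmorph_empty_error")
  mesh_from_facets(tri, frame)
}

# tri: (3*nfaces) x 3 matrix of vertex coordinates, rows grouped by facet.
mesh_from_facets <- function(tri, frame) {
  key <- paste(round(tri[, 1] * 1e6), round(tri[, 2] * 1e6), round(tri[, 3] * 1e6))
  idx <- match(key, key)                      # first occurrence per merged vertex
  keep <- !duplicated(idx)
  vertices <- tri[keep, , drop = FALSE]
  remap <- match(idx, which(keep))
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  # drop exactly duplicated facets (same ordered index triple)
  fkey <- paste(faces[, 1], faces[, 2], faces[, 3])
  faces <- faces[!duplicated(fkey), , drop = FALSE]
  triangle_mesh(vertices, faces, frame)
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) {
    stopf("corrupt binary STL %s: header truncated at byte %d (needs 84)",
          path, size, class = "epmorph_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n) || n < 0) stopf("corrupt binary STL %s: bad facet count at byte 80",
                               path, class = "epmorph_format_error")
  expected <- 84 + 50 * as.numeric(n)
  if (size < expected) {
    stopf("corrupt binary STL %s: facet block truncated at byte %d (expected %d)",
          path, size, expected, class = "epmorph_format_error")
  }
  if (n == 0) return(matrix(numeric(0), 0, 3))
  body <- readBin(con, "raw", n = 50L * n)
  offs <- rep.int((0:(n - 1)) * 50L, rep.int(48L, n)) + rep.int(1:48, n)
  vals <- readBin(body[offs], "double", n = 12L * n, size = 4L, endian = "little")
  m <- matrix(vals, nrow = 12L)               # cols = facets; rows 4:12 = vertices
  verts <- m[4:12, , drop = FALSE]
  matrix(as.vector(verts), ncol = 3, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines)
  if (length(vlines) %% 3 != 0) {
    stopf("corrupt ASCII STL %s: %d vertex records (not a multiple of 3, truncated near line %d)",
          path, length(vlines), max(vlines, 1L), class = "epmorph_format_error")
  }
  nf <- length(grep("^\\s*facet\\s+normal", lines))
  if (nf * 3 != length(vlines)) {
    stopf("corrupt ASCII STL %s: %d facet records but %d vertex triples",
          path, nf, length(vlines) / 3, class = "epmorph_format_error")
  }
  if (!length(vlines)) return(matrix(numeric(0), 0, 3))
  toks <- strsplit(trimws(lines[vlines]), "\\s+")
  bad <- which(lengths(toks) != 4)
  if (length(bad)) {
    stopf("corrupt ASCII STL %s: malformed vertex at line %d", path, vlines[bad[1]],
          class = "epmorph_format_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(lapply(toks, `[`, 2:4))))
  if (anyNA(vals)) {
    stopf("corrupt ASCII STL %s: non-numeric vertex coordinate", path,
          class = "epmorph_format_error")
  }
  matrix(vals, ncol = 3, byrow = TRUE)
}

#' Write a mesh to STL
#'
#' @param mesh a [triangle_mesh()]; must pass [validate_mesh()].
#' @param path output file path.
#' @param dialect `"binary"` (84-byte header + 50-byte facet records) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  rep_ok <- validate_mesh(mesh)
  if (!rep_ok$ok) {
    stopf("mesh fails validation (%d finding(s)); see validate_mesh()",
          nrow(rep_ok$findings), class = "epmorph_invalid_mesh")
  }
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)

  if (dialect == "binary") {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stopf("cannot open '%s' for writing", path,
                                              class = "epmorph_io_error"))
    on.exit(close(con))
    header <- charToRaw(formatC("epmorph surface mesh", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    rec <- t(cbind(nrm, p1, p2, p3))          # 12 floats per facet, column-major
    fr <- writeBin(as.numeric(rec), raw(), size = 4L, endian = "little")
    out <- matrix(as.raw(0), nrow = 50L, ncol = nrow(f))
    out[1:48, ] <- matrix(fr, nrow = 48L)
    writeBin(as.vector(out), con)
  } else {
    fmt_pt <- function(m) sprintf("      vertex %.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c("solid epmorph",
               as.vector(rbind(
                 sprintf("  facet normal %.9g %.9g %.9g", nrm[, 1], nrm[, 2], nrm[, 3]),
                 "    outer loop",
                 fmt_pt(p1), fmt_pt(p2), fmt_pt(p3),
                 "    endloop",
                 "  endfacet")),
               "endsolid epmorph")
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stopf("cannot open '%s' for writing", path, class = "epmorph_io_error")
  }
  invisible(path)
}
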