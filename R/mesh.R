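#' Anatomical coordinate frame for an endplate mesh
#'
#' STL files carry neither units nor axis conventions. `epmorph` fixes
#' millimetres and requires an explicit mapping from mesh coordinates to
#' anatomical directions. Each axis is given as a signed coordinate name,
#' e.g. `"+x"` meaning that increasing x points in that anatomical
#' direction.
#'
#' @param lateral signed axis pointing toward the patient's left
#'   (one of `"+x"`, `"-x"`, `"+y"`, `"-y"`, `"+z"`, `"-z"`).
#' @param ap signed axis pointing anteriorly.
#' @param si signed axis pointing superiorly.
#'
#' @return An object of class `anatomical_frame`: a named list with the
#'   three axis strings and a 3x3 rotation matrix `basis` whose rows map
#'   mesh xyz to (lateral, anterior, superior) coordinates.
#' @examples
#' anatomical_frame()                      # default: +x left, +y anterior, +z superior
#' anatomical_frame("-y", "+x", "+z")      # a rotated scanner convention
#' @export
anatomical_frame <- function(lateral = "+x", ap = "+y", si = "+z") {
  axes <- c(lateral = lateral, ap = ap, si = si)
  parsed <- lapply(axes, parse_axis)
  comps <- vapply(parsed, `[[`, integer(1), "component")
  if (anyDuplicated(comps)) {
    stopf("anatomical axes must name three distinct coordinate components (got %s)",
          paste(axes, collapse = ", "), class = "epmorph_frame_error")
  }
  basis <- matrix(0, 3, 3, dimnames = list(c("lateral", "ap", "si"), c("x", "y", "z")))
  for (i in seq_len(3)) basis[i, parsed[[i]]$component] <- parsed[[i]]$sign
  structure(list(lateral = lateral, ap = ap, si = si, basis = basis),
            class = "anatomical_frame")
}

parse_axis <- function(ax) {
  if (!is.character(ax) || length(ax) != 1 ||
      !grepl("^[+-]?[xyz]$", ax)) {
    stopf("axis must be one of '+x','-x','+y','-y','+z','-z' (got '%s')", ax,
          class = "epmorph_frame_error")
  }
  sign <- if (startsWith(ax, "-")) -1 else 1
  comp <- match(substr(ax, nchar(ax), nchar(ax)), c("x", "y", "z"))
  list(sign = sign, component = comp)
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> lateral(+left)=%s  ap(+anterior)=%s  si(+superior)=%s\n",
              x$lateral, x$ap, x$si))
  invisible(x)
}

#' Construct a triangulated surface mesh
#'
#' A minimal container for an endplate surface: vertex coordinates in
#' millimetres, triangular faces as 1-based vertex-index triples, and the
#' [anatomical_frame()] that orients it.
#'
#' @param vertices numeric matrix, n x 3, columns x/y/z in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param frame an [anatomical_frame()]; defaults to the package convention
#'   (+x left, +y anterior, +z superior).
#' @return An object of class `triangle_mesh`.
#' @seealso [read_stl()], [write_stl()], [validate_mesh()]
#' @export
triangle_mesh <- function(vertices, faces, frame = anatomical_frame()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stopf("vertices must have 3 columns")
  if (ncol(faces) != 3) stopf("faces must have 3 columns")
  if (!inherits(frame, "anatomical_frame")) stopf("frame must be an anatomical_frame")
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  print(x$frame)
  invisible(x)
}

#' Validate a triangle mesh
#'
#' Checks the structural invariants an endplate surface must satisfy before
#' measurement: all face indices in range, no degenerate triangles
#' (repeated vertex index or area below `1e-9` mm^2), all coordinates
#' finite. Always returns a report rather than erroring.
#'
#' @param mesh a [triangle_mesh()].
#' @return A list of class `mesh_validation` with elements `ok` (logical)
#'   and `findings`, a tibble with columns `type`, `index`, `detail`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
#' validate_mesh(m)$ok
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  findings <- list()
  add <- function(type, index, detail) {
    findings[[length(findings) + 1L]] <<- tibble(type = type, index = index, detail = detail)
  }

  bad_vert <- which(!is.finite(rowSums(v)))
  for (i in bad_vert) add("non_finite_vertex", i, "vertex has a non-finite coordinate")

  out_of_range <- which(apply(f, 1, function(r) any(r < 1L | r > nrow(v))))
  for (i in out_of_range) add("index_out_of_range", i, "face references a missing vertex")

  ok_faces <- setdiff(seq_len(nrow(f)), out_of_range)
  repeated <- ok_faces[f[ok_faces, 1] == f[ok_faces, 2] |
                         f[ok_faces, 2] == f[ok_faces, 3] |
                         f[ok_faces, 1] == f[ok_faces, 3]]
  for (i in repeated) add("degenerate_face", i, "face repeats a vertex index")

  area_faces <- setdiff(ok_faces, repeated)
  if (length(area_faces) && !length(bad_vert)) {
    a <- v[f[area_faces, 2], , drop = FALSE] - v[f[area_faces, 1], , drop = FALSE]
    b <- v[f[area_faces, 3], , drop = FALSE] - v[f[area_faces, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    areas <- 0.5 * sqrt(rowSums(cr^2))
    for (i in area_faces[areas < 1e-9]) add("degenerate_face", i, "face area below 1e-9 mm^2")
  }

  findings <- if (length(findings)) dplyr::bind_rows(findings) else {
    tibble(type = character(), index = integer(), detail = character())
  }
  structure(list(ok = nrow(findings) == 0L, findings = findings),
            class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  if (x$ok) cat("<mesh_validation> ok\n")
  else {
    cat(sprintf("<mesh_validation> %d finding(s)\n", nrow(x$findings)))
    print(x$findings)
  }
  invisible(x)
}

# Vertices expressed in the anatomical basis: columns lateral / ap / si.
anatomical_coords <- function(mesh) {
  mesh$vertices %*% t(mesh$frame$basis)
}
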