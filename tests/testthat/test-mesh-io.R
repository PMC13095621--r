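test_that("minimal ASCII STL reads to a 3-vertex, 1-face mesh", {
  f <- withr::local_tempfile(fileext = ".stl")
  single_facet_ascii(f)
  m <- read_stl(f)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
  expect_setequal(asplit(m$vertices, 1),
                  list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_true(validate_mesh(m)$ok)
})

test_that("write/read round-trips preserve geometry in both dialects", {
  m <- generate_surface(endplate_spec(depth_sagittal = 2, depth_coronal = 1.5,
                                      resolution = 16))
  for (dialect in c("binary", "ascii")) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_stl(m, f, dialect)
    m2 <- read_stl(f)   # auto-detected
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    expect_equal(nrow(m2$faces), nrow(m$faces))
    # stable ordering despite float32 perturbation of near-tied coordinates
    ord <- function(v) v[order(round(v[, 1], 3), round(v[, 2], 3), round(v[, 3], 3)), ]
    # binary STL stores float32: ~1e-6 relative on ~30 mm coordinates
    expect_lt(max(abs(ord(m2$vertices) - ord(m$vertices))), 5e-6)
  }
})

test_that("binary layout is 84 + 50 * n_faces bytes; ASCII has one facet record per face", {
  m <- generate_surface(endplate_spec(resolution = 16))
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, fb, "binary")
  write_stl(m, fa, "ascii")
  expect_identical(file.info(fb)$size, 84 + 50 * nrow(m$faces))
  expect_length(grep("^\\s*facet normal", readLines(fa)), nrow(m$faces))
})

test_that("synthetic surface at resolution 64 yields 2 * 63^2 faces through STL", {
  m <- generate_surface(endplate_spec(resolution = 64))
  expect_equal(nrow(m$faces), 2 * 63^2)
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, f, "binary")
  expect_equal(nrow(read_stl(f)$faces), 2 * 63^2)
})

test_that("shared vertices merge and exactly duplicated facets drop on read", {
  f <- withr::local_tempfile(fileext = ".stl")
  block <- c("  facet normal 0 0 1",
             "    outer loop",
             "      vertex 0 0 0",
             "      vertex 1 0 0",
             "      vertex 0 1 0",
             "    endloop",
             "  endfacet")
  block2 <- sub("vertex 0 0 0", "vertex 1 1 0", block)  # shares an edge
  writeLines(c("solid s", block, block, block2, "endsolid s"), f)
  m <- read_stl(f)
  expect_identical(nrow(m$faces), 2L)       # duplicate dropped
  expect_identical(nrow(m$vertices), 4L)    # shared edge merged
})

test_that("validate_mesh flags bad indices, degenerate faces and non-finite vertices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  good <- triangle_mesh(v, rbind(c(1, 2, 3)))
  expect_true(validate_mesh(good)$ok)

  rep_idx <- validate_mesh(triangle_mesh(v, rbind(c(1, 1, 2))))
  expect_false(rep_idx$ok)
  expect_true("degenerate_face" %in% rep_idx$findings$type)

  oob <- validate_mesh(triangle_mesh(v, rbind(c(1, 2, 9))))
  expect_true("index_out_of_range" %in% oob$findings$type)

  vbad <- v; vbad[2, 3] <- NaN
  nf <- validate_mesh(triangle_mesh(vbad, rbind(c(1, 2, 3))))
  expect_true("non_finite_vertex" %in% nf$findings$type)

  # zero-area triangle (three collinear points)
  vz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  za <- validate_mesh(triangle_mesh(vz, rbind(c(1, 2, 3))))
  expect_true("degenerate_face" %in% za$findings$type)

  expect_error(write_stl(triangle_mesh(v, rbind(c(1, 1, 2))), tempfile()),
               class = "epmorph_invalid_mesh")
})

test_that("corrupt and empty files raise informative format errors", {
  f <- withr::local_tempfile(fileext = ".stl")
  m <- generate_surface(endplate_spec(resolution = 16))
  write_stl(m, f, "binary")
  raw <- readBin(f, "raw", n = file.info(f)$size)
  writeBin(raw[1:200], f)   # truncate mid facet block
  expect_error(read_stl(f), "byte", class = "epmorph_format_error")

  f2 <- withr::local_tempfile(fileext = ".stl")
  file.create(f2)
  expect_error(read_stl(f2), class = "epmorph_empty_error")

  f3 <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid bad", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0",
               "    endloop", "  endfacet", "endsolid bad"), f3)
  expect_error(read_stl(f3), class = "epmorph_format_error")

  expect_error(read_stl(file.path(tempdir(), "nope.stl")),
               class = "epmorph_io_error")
})

test_that("anatomical frames demand three distinct signed axes", {
  fr <- anatomical_frame("-y", "+x", "+z")
  expect_equal(as.numeric(fr$basis %*% c(0, -1, 0)), c(1, 0, 0))
  expect_error(anatomical_frame("+x", "-x", "+z"), class = "epmorph_frame_error")
  expect_error(anatomical_frame("w", "+y", "+z"), class = "epmorph_frame_error")
})
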