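test_that("mid-plane sections reproduce the analytic height field", {
  flat <- generate_surface(endplate_spec(shape_class_sagittal = "flat",
                                         shape_class_coronal = "flat",
                                         depth_sagittal = 0, depth_coronal = 0,
                                         resolution = 24))
  p <- extract_profile(flat, "sagittal")
  expect_equal(diff(range(p$h)), 0)

  spec <- endplate_spec(depth_sagittal = 2,
                        shape_class_coronal = "flat", depth_coronal = 0,
                        resolution = 32)
  ps <- extract_profile(generate_surface(spec), "sagittal")
  expect_equal(min(ps$h), -2, tolerance = 0.02)
  expect_gt(nrow(ps), 3)
  expect_true(all(diff(ps$s) > 0))
})

test_that("rigid translation shifts the section but not the downstream metrics", {
  spec <- endplate_spec(depth_sagittal = 2, depth_coronal = 1.5, resolution = 32)
  m <- generate_surface(spec)
  m2 <- m
  m2$vertices <- m$vertices + matrix(rep(c(10, 10, 10), each = nrow(m$vertices)), ncol = 3)
  p1 <- extract_profile(m, "sagittal")
  p2 <- extract_profile(m2, "sagittal")
  expect_equal(p2$s - 10, p1$s, tolerance = 1e-9)
  expect_equal(p2$h - 10, p1$h, tolerance = 1e-9)
  met1 <- measure_profile(p1); met2 <- measure_profile(p2)
  for (col in c("chord_length", "concavity_depth", "length_end1", "length_end2",
                "ratio", "plateau_fraction")) {
    expect_equal(met2[[col]], met1[[col]], tolerance = 1e-9)
  }
})

test_that("the declared anatomical frame maps scanner axes onto the same profile", {
  spec <- endplate_spec(depth_sagittal = 2, depth_coronal = 1.2, resolution = 32)
  m <- generate_surface(spec)   # canonical: +x left, +y anterior, +z superior
  # re-express the mesh in a scanner convention: x' = -y, y' = x, z' = z
  v <- m$vertices
  m_rot <- triangle_mesh(cbind(-v[, 2], v[, 1], v[, 3]), m$faces,
                         frame = anatomical_frame(lateral = "+y", ap = "-x", si = "+z"))
  p1 <- extract_profile(m, "sagittal")
  p2 <- extract_profile(m_rot, "sagittal")
  expect_equal(p2$s, p1$s, tolerance = 1e-9)
  expect_equal(p2$h, p1$h, tolerance = 1e-9)
})

test_that("segment chaining conserves total intersection length", {
  spec <- endplate_spec(depth_sagittal = 2.5, depth_coronal = 2, noise_sd = 0.2,
                        resolution = 32, seed = 4)
  m <- generate_surface(spec)
  for (plane in c("sagittal", "coronal")) {
    segs <- epmorph:::profile_sections(m, plane)
    seg_total <- sum(sqrt((segs$s1 - segs$s2)^2 + (segs$h1 - segs$h2)^2))
    chains <- epmorph:::chain_segments(segs)
    chain_total <- sum(vapply(chains, epmorph:::polyline_length, numeric(1)))
    expect_equal(chain_total, seg_total, tolerance = 1e-9)
  }
})

test_that("profiles converge to the analytic mid-line as resolution doubles", {
  err_at <- function(res) {
    spec <- endplate_spec(depth_sagittal = 3,
                          shape_class_coronal = "flat", depth_coronal = 0,
                          resolution = res)
    p <- extract_profile(generate_surface(spec), "sagittal")
    analytic <- -3 * epmorph:::bump_shape(p$s, 50, 0)
    max(abs(p$h - analytic))
  }
  errs <- vapply(c(16, 32, 64), err_at, numeric(1))
  expect_lt(errs[2], errs[1] / 2)
  expect_lt(errs[3], errs[2] / 2)
})

test_that("degenerate sections raise typed errors", {
  # two tiny triangles far to either side: the mid-plane misses both
  v <- rbind(c(-10, 0, 0), c(-10, 1, 0), c(-10, 0.5, 1),
             c(10, 0, 0), c(10, 1, 0), c(10, 0.5, 1))
  m <- triangle_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(extract_profile(m, "sagittal"), class = "epmorph_no_section")
})

test_that("profiles round-trip through 2-column CSV", {
  p <- generate_profile(endplate_spec(depth_sagittal = 2, resolution = 33), "coronal")
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  p2 <- read_profile_csv(f, "coronal")
  expect_equal(p2$s, p$s)
  expect_equal(p2$h, p$h)
  expect_identical(attr(p2, "end_labels"), c("right", "left"))
})

test_that("profile construction enforces its invariants", {
  expect_error(as_profile(data.frame(s = c(0, 1), h = c(0, 0)), "sagittal"),
               class = "epmorph_degenerate_section")
  expect_error(as_profile(data.frame(s = c(0, 1, NA), h = c(0, 0, 0)), "sagittal"),
               class = "epmorph_input_error")
  p <- as_profile(data.frame(s = c(3, 1, 2), h = c(1, 2, 3)), "sagittal")
  expect_equal(p$s, c(1, 2, 3))  # sorted on construction
})
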