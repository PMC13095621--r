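test_that("noise-free profiles realise their archetype exactly", {
  # uniform: apex on the sample grid (odd resolution), min height -D at s = 0
  p <- generate_profile(endplate_spec(depth_sagittal = 2, resolution = 65), "sagittal")
  expect_equal(min(p$h), -2)
  expect_equal(p$s[which.min(p$h)], 0)
  expect_equal(p$h[c(1, nrow(p))], c(0, 0))   # endpoints exact before noise

  # flat with a sub-millimetre depression stays within its depth
  pf <- generate_profile(endplate_spec(shape_class_sagittal = "flat",
                                       depth_sagittal = 0.3, resolution = 65),
                         "sagittal")
  expect_lte(max(abs(pf$h)), 0.3)

  # flat-bottomed: full-depth plateau of the requested fraction
  pb <- generate_profile(endplate_spec(shape_class_sagittal = "flat_bottom",
                                       depth_sagittal = 2, plateau_fraction = 0.4,
                                       resolution = 201), "sagittal")
  at_depth <- range(pb$s[pb$h <= -2 + 1e-9])
  expect_equal(diff(at_depth) / 50, 0.4, tolerance = 0.02)
})

test_that("asymmetric profile with apex at 35% of the chord measures ratio >= 1.3", {
  # apex offset -0.15: apex 35% of the chord from the posterior margin
  spec <- endplate_spec(shape_class_sagittal = "asymmetric_concave",
                        depth_sagittal = 1.5, apex_offset_sagittal = -0.15,
                        resolution = 201)
  p <- generate_profile(spec, "sagittal")
  m <- measure_profile(p)
  expect_equal(m$concavity_depth, 1.5, tolerance = 1e-6)
  expect_gte(m$ratio, 1.3)
  # brute force over the polyline: deepest point by exact point-to-chord distance
  chord <- c(diff(range(p$s)), 0)
  d_bf <- abs(p$h - 0)          # margins at h = 0: perpendicular = |h|
  expect_equal(m$apex_s, p$s[which.max(d_bf)])
})

test_that("spec validation enforces class/parameter consistency", {
  expect_error(endplate_spec(shape_class_sagittal = "flat", depth_sagittal = 1.2),
               class = "epmorph_parameter_error")
  expect_error(endplate_spec(depth_sagittal = 0.5),  # uniform needs >= 1
               class = "epmorph_parameter_error")
  expect_error(endplate_spec(shape_class_sagittal = "asymmetric_concave",
                             depth_sagittal = 2, apex_offset_sagittal = 0),
               class = "epmorph_parameter_error")
  expect_error(endplate_spec(depth_sagittal = 2, apex_offset_sagittal = 0.3),
               class = "epmorph_parameter_error")  # uniform with ratio >= 1.3
  expect_error(endplate_spec(resolution = 8), class = "epmorph_parameter_error")
  expect_gte(induced_ratio(0.15, 1.5, 50), 1.3)
  expect_lt(induced_ratio(0.03, 2, 50), 1.3)
})

test_that("surfaces realise the specified per-plane depths and face count", {
  spec <- endplate_spec(depth_sagittal = 2, depth_coronal = 3, resolution = 48)
  surf <- generate_surface(spec)
  expect_equal(nrow(surf$faces), 2 * 47^2)
  tol <- max(0.05, 50 / 48)
  ms <- measure_profile(extract_profile(surf, "sagittal"))
  mc <- measure_profile(extract_profile(surf, "coronal"))
  expect_equal(ms$concavity_depth, 2, tolerance = tol / 2)
  expect_equal(mc$concavity_depth, 3, tolerance = tol / 3)

  flat <- generate_surface(endplate_spec(shape_class_sagittal = "flat",
                                         shape_class_coronal = "flat",
                                         depth_sagittal = 0, depth_coronal = 0,
                                         resolution = 24))
  expect_equal(diff(range(flat$vertices[, 3])), 0)
})

test_that("generation is deterministic in the seed", {
  spec1 <- endplate_spec(depth_sagittal = 2, noise_sd = 0.1, seed = 11)
  spec2 <- endplate_spec(depth_sagittal = 2, noise_sd = 0.1, seed = 12)
  expect_identical(generate_surface(spec1)$vertices, generate_surface(spec1)$vertices)
  expect_false(identical(generate_surface(spec1)$vertices,
                         generate_surface(spec2)$vertices))
  expect_identical(generate_profile(spec1, "sagittal"),
                   generate_profile(spec1, "sagittal"))
})

test_that("measured depth tracks the generator depth on noise-free surfaces", {
  depths <- c(1.2, 2, 3, 3.8)
  res <- 40
  errs <- vapply(depths, function(d) {
    surf <- generate_surface(endplate_spec(depth_sagittal = d, depth_coronal = d,
                                           resolution = res))
    m <- measure_profile(extract_profile(surf, "sagittal"))
    abs(m$concavity_depth - d)
  }, numeric(1))
  expect_lt(max(errs), max(0.05, 50 / res))
  # monotone recovery
  meas <- vapply(depths, function(d) {
    measure_profile(generate_profile(
      endplate_spec(depth_sagittal = d, resolution = 65), "sagittal"))$concavity_depth
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})

test_that("cohorts have 5 endplates per patient with consistent labels", {
  coh <- generate_cohort(n_patients = 2, seed = 5, resolution = 24)
  expect_identical(nrow(coh), 10L)
  expect_equal(as.integer(table(coh$patient)), c(5L, 5L))
  expect_setequal(unique(coh$segment),
                  c("L4 sup", "L4 inf", "L5 sup", "L5 inf", "S1 sup"))

  single <- generate_cohort(n_patients = 1, seed = 5, resolution = 24)
  expect_identical(nrow(single), 5L)

  all_flat <- tibble::tibble(segment = c("L4 sup", "L4 inf", "L5 sup", "L5 inf", "S1 sup"),
                             uniform_concave = 0, asymmetric_concave = 0,
                             flat_bottom = 0, flat = 1)
  coh_flat <- generate_cohort(n_patients = 2, seed = 5, resolution = 24,
                              class_mix_sagittal = all_flat,
                              class_mix_coronal = all_flat)
  expect_true(all(coh_flat$true_class_sagittal == "flat"))
  expect_true(all(coh_flat$true_depth_sagittal < 1))

  bad_mix <- all_flat; bad_mix$flat <- -1
  expect_error(generate_cohort(2, class_mix_sagittal = bad_mix),
               class = "epmorph_parameter_error")
})

test_that("cohort generation is order-independent through derived seeds", {
  coh <- generate_cohort(n_patients = 3, seed = 9, resolution = 24)
  # a smaller cohort regenerates patient 1's endplates bit-identically
  coh2 <- generate_cohort(n_patients = 2, seed = 9, resolution = 24)
  i <- which(coh$patient == "P001")[1]
  j <- which(coh2$patient == "P001")[1]
  expect_identical(coh$mesh[[i]]$vertices, coh2$mesh[[j]]$vertices)
})

test_that("cohort round-trips through an STL directory with manifest", {
  coh <- generate_cohort(n_patients = 2, seed = 3, resolution = 24)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(nrow(back), 10L)
  expect_identical(back$true_class_sagittal, coh$true_class_sagittal)
  ord <- function(v) v[order(round(v[, 1], 3), round(v[, 2], 3), round(v[, 3], 3)), ]
  expect_equal(ord(back$mesh[[1]]$vertices), ord(unname(coh$mesh[[1]]$vertices)),
               tolerance = 1e-5, ignore_attr = TRUE)

  file.remove(file.path(dir, back$file[1]))
  expect_error(read_cohort(dir), class = "epmorph_io_error")
})
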