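# Published summary rows are rounded to 2 decimals, so statistics recomputed
# from them can differ from the printed test columns by slightly more than
# half an ulp; 0.01 absorbs that input rounding.
tol_printed <- 0.01

test_that("pooled t-test reproduces the published sex-comparison rows", {
  rows <- tibble::tribble(
    ~g1,                      ~g2,                      ~t,     ~d,     ~lo,    ~hi,
    list(19, 1.77, 0.56),     list(14, 2.06, 0.43),     -1.61,  -0.57,  -0.66,  0.08,  # sagittal L4 inf
    list(19, 0.63, 0.65),     list(14, 0.44, 0.25),      1.03,   0.36,     NA,    NA,  # sagittal S1 sup
    list(19, 3.16, 0.99),     list(14, 3.43, 1.15),     -0.72,  -0.25,  -1.03,  0.49)  # coronal L4 inf
  for (i in seq_len(nrow(rows))) {
    fit <- pooled_t_test(group_summary(rows$g1[[i]][[1]], rows$g1[[i]][[2]], rows$g1[[i]][[3]]),
                         group_summary(rows$g2[[i]][[1]], rows$g2[[i]][[2]], rows$g2[[i]][[3]]))
    expect_equal(fit$t, rows$t[i], tolerance = tol_printed / abs(rows$t[i]))
    expect_equal(fit$cohens_d, rows$d[i], tolerance = tol_printed / abs(rows$d[i]))
    if (!is.na(rows$lo[i])) {
      expect_equal(fit$ci_low, rows$lo[i], tolerance = tol_printed / abs(rows$lo[i]))
      expect_equal(fit$ci_high, rows$hi[i], tolerance = tol_printed / abs(rows$hi[i]))
    }
    expect_equal(fit$df, rows$g1[[i]][[1]] + rows$g2[[i]][[1]] - 2)
  }
})

test_that("summary-statistics t-test equals the raw-sample t-test", {
  set.seed(41)
  for (rep in 1:4) {
    x <- rnorm(17, 1.8, 0.6); y <- rnorm(12, 2.1, 0.5)
    fit <- pooled_t_test(summarize_group(x), summarize_group(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(fit$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(fit$p, ref$p.value, tolerance = 1e-12)
    expect_equal(c(fit$ci_low, fit$ci_high), as.numeric(ref$conf.int), tolerance = 1e-12)
  }
})

test_that("pooled t-test is antisymmetric and handles degenerate input", {
  g1 <- group_summary(10, 2.0, 0.5); g2 <- group_summary(12, 1.6, 0.7)
  a <- pooled_t_test(g1, g2); b <- pooled_t_test(g2, g1)
  expect_equal(a$t, -b$t)
  expect_equal(a$cohens_d, -b$cohens_d)
  expect_equal(a$ci_low, -b$ci_high)

  same <- pooled_t_test(g1, g1)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$ci_low, -same$ci_high)

  z <- group_summary(5, 1, 0)
  expect_equal(pooled_t_test(z, z)$t, 0)
  expect_error(pooled_t_test(z, group_summary(5, 2, 0)),
               class = "epmorph_degenerate_error")
})

test_that("Cramer's V reproduces the published morphology effect sizes", {
  # sagittal L4 sup
  expect_equal(chi_square_cramers_v(rbind(c(4, 5, 2, 8), c(5, 2, 5, 2)))$cramers_v,
               0.41, tolerance = 0.005 / 0.41)
  # coronal L5 sup: one all-zero column dropped
  v2 <- chi_square_cramers_v(rbind(c(0, 0, 11, 8), c(2, 0, 9, 3)))
  expect_identical(v2$effective_dims, c(2L, 3L))
  expect_equal(v2$cramers_v, 0.34, tolerance = 0.005 / 0.34)
  # coronal S1 sup: two all-zero columns dropped
  v3 <- chi_square_cramers_v(rbind(c(13, 0, 6, 0), c(7, 0, 7, 0)))
  expect_identical(v3$effective_dims, c(2L, 2L))
  expect_equal(v3$cramers_v, 0.19, tolerance = 0.005 / 0.19)
})

test_that("Cramer's V is 1 for perfect association, bounded, permutation-invariant", {
  expect_equal(chi_square_cramers_v(rbind(c(5, 0), c(0, 5)))$cramers_v, 1)
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(rpois(8, 4), 2, 4)
    m[1, 1] <- m[1, 1] + 1     # guard against all-zero
    v <- chi_square_cramers_v(m)$cramers_v
    expect_gte(v, 0); expect_lte(v, 1)
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(chi_square_cramers_v(perm)$cramers_v, v, tolerance = 1e-12)
  }
  expect_error(chi_square_cramers_v(rbind(c(3, 0), c(4, 0))),
               class = "epmorph_undefined_effect")
})

test_that("Freeman-Halton exact test reproduces the published p and its oracles", {
  t4 <- rbind(c(4, 5, 2, 8), c(5, 2, 5, 2))
  fh <- freeman_halton_exact(t4)
  expect_equal(fh$p_exact, 0.14, tolerance = 0.005 / 0.14)
  # total enumeration mass is 1
  expect_equal(fh$prob_total, 1, tolerance = 1e-10)
  # equally probable 2x2 tables
  expect_equal(freeman_halton_exact(rbind(c(1, 0), c(0, 1)))$p_exact, 1)
})

test_that("exact p matches independent enumeration and fisher.test on small tables", {
  set.seed(11)
  for (rep in 1:6) {
    m <- matrix(rmultinom(1, 20, rep(1 / 6, 6)), nrow = 2)
    fh <- freeman_halton_exact(m)
    expect_equal(fh$p_exact, fh_oracle_2xc(m), tolerance = 1e-12)
    expect_equal(fh$p_exact, fisher.test(m)$p.value, tolerance = 1e-7)
  }
  # 2x2 case equals the classical Fisher two-sided p
  for (rep in 1:6) {
    m <- matrix(rmultinom(1, 16, rep(0.25, 4)), nrow = 2) + 1
    expect_equal(freeman_halton_exact(m)$p_exact, fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("exact p is invariant to all-zero rows and columns", {
  m <- rbind(c(4, 5, 2, 8), c(5, 2, 5, 2))
  padded <- cbind(rbind(m, 0), 0)
  expect_equal(freeman_halton_exact(padded)$p_exact,
               freeman_halton_exact(m)$p_exact, tolerance = 1e-15)
  expect_error(freeman_halton_exact(matrix(200, 2, 2) + diag(2)),
               class = "epmorph_resource_error")
})

test_that("ICC(A,1) matches its ANOVA decomposition and analytic recovery", {
  # identical raters agree perfectly
  r <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(icc_absolute_agreement(r)$icc, 1)

  # mean squares agree with stats::aov on a small example
  set.seed(13)
  x <- matrix(rnorm(24), 8, 3)
  fit <- icc_absolute_agreement(x)
  long <- data.frame(y = as.vector(x),
                     subj = factor(rep(1:8, 3)), rater = factor(rep(1:3, each = 8)))
  ms <- anova(aov(y ~ subj + rater, data = long))[["Mean Sq"]]
  expect_equal(fit$msr, ms[1], tolerance = 1e-10)
  expect_equal(fit$msc, ms[2], tolerance = 1e-10)
  expect_equal(fit$mse, ms[3], tolerance = 1e-10)

  # two-way random simulation: ICC near sigma_s^2 / (sigma_s^2 + sigma_r^2 + sigma_e^2)
  set.seed(99)
  n <- 50; k <- 2
  subj <- rnorm(n, 0, 1.0); rater <- rnorm(k, 0, 0.1)
  y <- outer(subj, rater, "+") + matrix(rnorm(n * k, 0, 0.3), n, k)
  analytic <- 1 / (1 + 0.1^2 + 0.3^2)
  expect_equal(icc_absolute_agreement(y)$icc, analytic, tolerance = 0.1 / analytic)

  # zero between-subject variance degrades to 0 with a warning
  flat <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_warning(z <- icc_absolute_agreement(flat), "between-subject")
  expect_equal(z$icc, 0)
})
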