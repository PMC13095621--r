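#' Group summary statistics
#'
#' A group described by its size, mean and standard deviation — the form
#' in which cohort depth comparisons are published.
#'
#' @param n group size (>= 2).
#' @param mean group mean (mm).
#' @param sd group standard deviation (mm, >= 0).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2",
                                   class = "epmorph_parameter_error")
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stopf("mean must be finite and sd >= 0", class = "epmorph_parameter_error")
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd), class = "group_summary")
}

#' Summarise a raw sample as a group_summary
#' @param x numeric vector.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x) group_summary(length(x), mean(x), sd(x))

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  if (is.list(g) && all(c("n", "mean", "sd") %in% names(g))) {
    return(group_summary(g$n, g$mean, g$sd))
  }
  stopf("expected a group_summary or a list with n, mean, sd",
        class = "epmorph_parameter_error")
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's independent-sample t-test on the pooled variance
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, with the
#' confidence interval of the mean difference and Cohen's d
#' (`(m1 - m2) / sp`). The pooled (not Welch) form is used because it is
#' the convention under which the reference cohort's published t and d
#' values reproduce.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `n`, `mean`,
#'   `sd`).
#' @param conf_level confidence level for the CI of the mean difference.
#' @return An object of class `epmorph_ttest` with fields `estimate`
#'   (mean difference), `t`, `df`, `p`, `ci_low`, `ci_high`, `cohens_d`.
#' @examples
#' fit <- pooled_t_test(group_summary(19, 1.77, 0.56),
#'                      group_summary(14, 2.06, 0.43))
#' tidy(fit)
#' @export
pooled_t_test <- function(g1, g2, conf_level = 0.95) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  df <- g1$n + g2$n - 2L
  if (df <= 0) stopf("need n1 + n2 > 2", class = "epmorph_degenerate_error")
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  est <- g1$mean - g2$mean
  if (sp2 == 0) {
    if (est == 0) {
      t <- 0; d <- 0; se <- 0
    } else {
      stopf("both groups have zero variance but different means",
            class = "epmorph_degenerate_error")
    }
  } else {
    sp <- sqrt(sp2)
    se <- sp * sqrt(1 / g1$n + 1 / g2$n)
    t <- est / se
    d <- est / sp
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  p <- 2 * pt(-abs(t), df)
  structure(list(estimate = est, t = t, df = df, p = p,
                 ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                 cohens_d = d, conf_level = conf_level,
                 g1 = g1, g2 = g2),
            class = "epmorph_ttest")
}

#' @export
print.epmorph_ttest <- function(x, ...) {
  cat(sprintf("Pooled two-sample t-test: t = %.3f, df = %d, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  diff = %.3f  %g%% CI [%.3f, %.3f]  Cohen's d = %.3f\n",
              x$estimate, 100 * x$conf_level, x$ci_low, x$ci_high, x$cohens_d))
  invisible(x)
}

#' @export
tidy.epmorph_ttest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$t, df = x$df, p.value = x$p,
         conf.low = x$ci_low, conf.high = x$ci_high, cohens_d = x$cohens_d)
}

#' @export
glance.epmorph_ttest <- function(x, ...) tidy(x)

drop_zero_margins <- function(m) {
  m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
}

as_count_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stopf("contingency counts must be finite non-negative integers",
          class = "epmorph_input_error")
  }
  if (sum(m) <= 0) stopf("contingency table has no positive count",
                         class = "epmorph_input_error")
  m
}

#' Chi-square statistic with Cramér's V
#'
#' Pearson chi-square on a contingency table (no continuity correction)
#' with Cramér's V effect size, `V = sqrt(chi2 / (N (min(r', c') - 1)))`.
#' All-zero rows and columns are removed first — required to avoid zero
#' expected counts, and the convention under which the reference cohort's
#' published V values reproduce.
#'
#' @param x contingency counts (matrix, table, or data frame of counts).
#' @return A list of class `epmorph_chisq`: `chi2`, `df`, `p`,
#'   `cramers_v`, `n`, `effective_dims`.
#' @examples
#' chi_square_cramers_v(rbind(c(4, 5, 2, 8), c(5, 2, 5, 2)))$cramers_v
#' @export
chi_square_cramers_v <- function(x) {
  m <- drop_zero_margins(as_count_matrix(x))
  if (nrow(m) < 2 || ncol(m) < 2) {
    stopf("table reduces below 2x2 after dropping empty categories; effect size undefined",
          class = "epmorph_undefined_effect")
  }
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  chi2 <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  structure(list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
                 cramers_v = sqrt(chi2 / (n * (min(dim(m)) - 1))),
                 n = n, effective_dims = dim(m)),
            class = "epmorph_chisq")
}

#' @export
print.epmorph_chisq <- function(x, ...) {
  cat(sprintf("Chi-square: X2 = %.3f, df = %d, p = %.4g, Cramer's V = %.3f (on %dx%d, N = %d)\n",
              x$chi2, x$df, x$p, x$cramers_v,
              x$effective_dims[1], x$effective_dims[2], x$n))
  invisible(x)
}

#' @export
tidy.epmorph_chisq <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p, cramers_v = x$cramers_v,
         n = x$n)
}

#' Freeman–Halton exact test for r x c tables
#'
#' Generalises Fisher's exact test to r x c tables by exhaustively
#' enumerating every table with the observed margins. Each table's
#' probability under the multivariate hypergeometric null is
#' `prod(rowsum_i!) prod(colsum_j!) / (N! prod(a_ij!))`; the two-sided p
#' is the total probability of tables no more probable than the observed
#' one (a relative slack of 1e-12 on the comparison absorbs
#' floating-point ties). All-zero rows and columns are dropped first,
#' which cannot change p. Also reports the chi-square Cramér's V of the
#' reduced table when defined.
#'
#' @param x contingency counts.
#' @param n_max enumeration budget: maximum table total N (the default
#'   200 is comfortable for 2 x 4 tables; larger tables grow
#'   combinatorially).
#' @return A list of class `epmorph_fh`: `p_exact`, `chi2`, `cramers_v`,
#'   `effective_dims`, `n_tables`, `prob_total` (enumeration mass, ~1).
#' @examples
#' freeman_halton_exact(rbind(c(4, 5, 2, 8), c(5, 2, 5, 2)))$p_exact
#' @export
freeman_halton_exact <- function(x, n_max = 200) {
  m <- drop_zero_margins(as_count_matrix(x))
  n <- sum(m)
  if (n > n_max) {
    stopf("table total N = %d exceeds the enumeration budget (%d); consider chi_square_cramers_v()",
          n, n_max, class = "epmorph_resource_error")
  }
  cv <- tryCatch(chi_square_cramers_v(m), error = function(e) NULL)
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(structure(list(p_exact = 1, chi2 = NA_real_, cramers_v = NA_real_,
                          effective_dims = dim(m), n_tables = 1L, prob_total = 1),
                     class = "epmorph_fh"))
  }
  rt <- rowSums(m); ct <- colSums(m)
  log_const <- sum(lgamma(rt + 1)) + sum(lgamma(ct + 1)) - lgamma(n + 1)
  logp_obs <- log_const - sum(lgamma(m + 1))
  logps <- enumerate_fixed_margin_logps(rt, ct, log_const)
  probs <- exp(logps)
  p <- sum(probs[logps <= logp_obs + 1e-12 * abs(logp_obs) + 1e-300])
  structure(list(p_exact = min(p, 1),
                 chi2 = if (is.null(cv)) NA_real_ else cv$chi2,
                 cramers_v = if (is.null(cv)) NA_real_ else cv$cramers_v,
                 effective_dims = dim(m),
                 n_tables = length(logps),
                 prob_total = sum(probs)),
            class = "epmorph_fh")
}

# log-probabilities of every table with the given margins
enumerate_fixed_margin_logps <- function(rt, ct, log_const) {
  r <- length(rt)
  acc <- new.env(parent = emptyenv())
  acc$v <- numeric(0)
  recurse_rows <- function(i, rem, log_acc) {
    if (i == r) {
      acc$v <- c(acc$v, log_acc - sum(lgamma(rem + 1)))
      return(invisible())
    }
    for (comp in bounded_compositions(rt[i], rem)) {
      recurse_rows(i + 1L, rem - comp, log_acc - sum(lgamma(comp + 1)))
    }
  }
  recurse_rows(1L, ct, log_const)
  acc$v
}

# all vectors a with 0 <= a_j <= bounds_j and sum(a) == total
bounded_compositions <- function(total, bounds) {
  c_ <- length(bounds)
  out <- list()
  rec <- function(j, left, acc) {
    if (j == c_) {
      if (left <= bounds[j]) out[[length(out) + 1L]] <<- c(acc, left)
      return(invisible())
    }
    tail_cap <- sum(bounds[(j + 1):c_])
    lo <- max(0L, left - tail_cap)
    hi <- min(bounds[j], left)
    if (hi < lo) return(invisible())
    for (a in lo:hi) rec(j + 1L, left - a, c(acc, a))
  }
  rec(1L, total, integer(0))
  out
}

#' @export
print.epmorph_fh <- function(x, ...) {
  cat(sprintf("Freeman-Halton exact test: p = %.4g (enumerated %d tables on %dx%d)\n",
              x$p_exact, x$n_tables, x$effective_dims[1], x$effective_dims[2]))
  if (is.finite(x$cramers_v)) cat(sprintf("  Cramer's V = %.3f\n", x$cramers_v))
  invisible(x)
}

#' @export
tidy.epmorph_fh <- function(x, ...) {
  tibble(p.value = x$p_exact, cramers_v = x$cramers_v, chi2 = x$chi2,
         n_tables = x$n_tables)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-rater absolute-agreement ICC — ICC(A,1) — from the two-way
#' ANOVA decomposition of an n-subjects x k-raters rating matrix:
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, raters
#'   in columns; no missing cells; at least 2 of each.
#' @return A list of class `epmorph_icc`: `icc`, `model`, mean squares,
#'   variance components (`sigma2_rows`, `sigma2_raters`,
#'   `sigma2_error`), `n`, `k`.
#' @examples
#' r <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 2.9, 4.2))
#' icc_absolute_agreement(r)$icc
#' @export
icc_absolute_agreement <- function(ratings) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  if (anyNA(x)) stopf("ratings must have no missing cells", class = "epmorph_input_error")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stopf("need at least 2 subjects and 2 raters",
                            class = "epmorph_parameter_error")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (var(rowm) == 0) {
    warn("zero between-subject variance; ICC set to 0")
    icc <- 0
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  structure(list(icc = icc,
                 model = "two-way random effects, absolute agreement, single rater (ICC(A,1))",
                 msr = msr, msc = msc, mse = mse,
                 sigma2_rows = (msr - mse) / k,
                 sigma2_raters = max((msc - mse) / n, 0),
                 sigma2_error = mse,
                 n = n, k = k),
            class = "epmorph_icc")
}

#' @export
print.epmorph_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f  [%s]\n", x$icc, x$model))
  cat(sprintf("  n = %d subjects, k = %d raters; var components: subjects %.4g, raters %.4g, error %.4g\n",
              x$n, x$k, x$sigma2_rows, x$sigma2_raters, x$sigma2_error))
  invisible(x)
}

#' @export
tidy.epmorph_icc <- function(x, ...) {
  tibble(icc = x$icc, sigma2_rows = x$sigma2_rows,
         sigma2_raters = x$sigma2_raters, sigma2_error = x$sigma2_error,
         n = x$n, k = x$k)
}
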