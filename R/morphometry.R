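#' Locate the margin (chord) points of a profile
#'
#' The measurement chord connects the highest points of the two margins.
#' To keep this robust on tilted profiles the search for each margin's
#' highest point is restricted to the outer `margin_fraction` of the
#' profile's extent, and both the windows and "highest" are defined
#' relative to the line joining the profile's two endpoints (position
#' along it, height normal to it), which makes the margin choice — and
#' hence every chord-derived metric — invariant under rigid motions of
#' the profile. Ties go to the outermost point. For an anatomically
#' oriented profile the endpoint line is horizontal and this reduces to
#' "maximum h in each terminal window".
#'
#' @param profile an `endplate_profile` (see [as_profile()]).
#' @param margin_fraction width of each terminal search window as a
#'   fraction of the span; must be below 0.5 so the windows cannot
#'   overlap.
#' @return A tibble with two rows (`end`, `s`, `h`): the first row is the
#'   posterior (sagittal) or right (coronal) margin.
#' @export
find_margin_points <- function(profile, margin_fraction = 0.15) {
  if (margin_fraction >= 0.5 || margin_fraction <= 0) {
    stopf("margin_fraction must be in (0, 0.5) so the margin windows cannot overlap",
          class = "epmorph_parameter_error")
  }
  s <- profile$s; h <- profile$h
  n <- length(s)
  u <- c(s[n] - s[1], h[n] - h[1])
  u <- u / sqrt(sum(u^2))
  up <- c(-u[2], u[1])                      # normal, superior-pointing (u[1] > 0)
  t <- (s - s[1]) * u[1] + (h - h[1]) * u[2]
  elev <- (s - s[1]) * up[1] + (h - h[1]) * up[2]
  span <- max(t) - min(t)
  w1 <- which(t <= min(t) + margin_fraction * span)
  w2 <- which(t >= max(t) - margin_fraction * span)
  # highest elevation in each window; ties broken toward the outer end
  best1 <- max(elev[w1])
  i1 <- w1[which(elev[w1] == best1)]
  i1 <- i1[which.min(t[i1])]
  best2 <- max(elev[w2])
  i2 <- w2[which(elev[w2] == best2)]
  i2 <- i2[which.max(t[i2])]
  labels <- attr(profile, "end_labels") %||% c("end1", "end2")
  tibble(end = labels, s = c(s[i1], s[i2]), h = c(h[i1], h[i2]))
}

#' Measure the concavity parameters of a profile
#'
#' Computes the standard endplate concavity parameters from a mid-plane
#' profile. With the chord defined by [find_margin_points()]:
#'
#' * `chord_length` — Euclidean distance between the margin points (the
#'   sagittal or coronal diameter, SD / CD);
#' * `concavity_depth` — maximum perpendicular distance from the chord to
#'   profile points on its inferior side (SCD / CCD); 0 if no point lies
#'   below the chord;
#' * `length_end1`, `length_end2` — straight-line distances from the
#'   deepest point (apex) to the posterior/anterior (sagittal) or
#'   right/left (coronal) margin points (SPL and SAL, or CRL and CLL);
#' * `ratio` — the larger over the smaller of those two lengths
#'   (defined as 1 for a profile with zero depth);
#' * `plateau_fraction` — chord-projected extent of the points whose
#'   perpendicular depth is at least `plateau_level` times the maximum,
#'   as a fraction of the chord span (drives the flat-bottom rule).
#'
#' Depth is measured perpendicular to the chord in both planes, which
#' makes every parameter invariant under rigid motions of the profile.
#' Convex profiles get depth 0, ratio 1 and the apex at the chord
#' midpoint.
#'
#' @inheritParams find_margin_points
#' @param plateau_level depth fraction defining the plateau (default 0.9).
#' @return A one-row tibble with the metrics plus `apex_s`, `apex_h`,
#'   `margin1_s/h`, `margin2_s/h`, `plane`.
#' @examples
#' # lower semicircle of radius 5: chord 10, depth 5, equal lengths sqrt(50)
#' th <- seq(pi, 2 * pi, length.out = 201)
#' p <- as_profile(data.frame(s = 5 * cos(th), h = 5 * sin(th)), "sagittal")
#' measure_profile(p)[, c("chord_length", "concavity_depth", "ratio")]
#' @export
measure_profile <- function(profile, margin_fraction = 0.15, plateau_level = 0.9) {
  margins <- find_margin_points(profile, margin_fraction)
  s <- profile$s; h <- profile$h
  m1 <- c(margins$s[1], margins$h[1])
  m2 <- c(margins$s[2], margins$h[2])
  u <- m2 - m1
  clen <- sqrt(sum(u^2))
  if (clen <= 0) stopf("margin points coincide", class = "epmorph_degenerate_section")

  t <- ((s - m1[1]) * u[1] + (h - m1[2]) * u[2]) / clen^2
  signed <- (u[1] * (h - m1[2]) - u[2] * (s - m1[1])) / clen
  between <- t >= 0 & t <= 1
  if (sum(between) < 3) {
    stopf("fewer than 3 profile points between the margin points",
          class = "epmorph_degenerate_section")
  }
  depth_i <- ifelse(between, -signed, -Inf)
  depth <- max(depth_i)

  if (depth <= 0) {
    depth <- 0
    apex <- (m1 + m2) / 2
    len1 <- len2 <- clen / 2
    ratio <- 1
    plateau <- 0
  } else {
    ai <- which.max(depth_i)
    apex <- c(s[ai], h[ai])
    len1 <- sqrt(sum((apex - m1)^2))
    len2 <- sqrt(sum((apex - m2)^2))
    ratio <- max(len1, len2) / min(len1, len2)
    qual <- t[between & depth_i >= plateau_level * depth]
    plateau <- if (length(qual)) max(qual) - min(qual) else 0
  }

  tibble(chord_length = clen,
         concavity_depth = depth,
         length_end1 = len1,
         length_end2 = len2,
         ratio = ratio,
         plateau_fraction = plateau,
         apex_s = apex[1], apex_h = apex[2],
         margin1_s = m1[1], margin1_h = m1[2],
         margin2_s = m2[1], margin2_h = m2[2],
         plane = profile_plane(profile) %||% NA_character_)
}

#' Measure both mid-plane profiles of an endplate mesh
#'
#' @param mesh a [triangle_mesh()].
#' @inheritParams measure_profile
#' @return A two-row tibble (sagittal then coronal metrics).
#' @export
measure_endplate <- function(mesh, margin_fraction = 0.15, plateau_level = 0.9) {
  dplyr::bind_rows(lapply(c("sagittal", "coronal"), function(pl) {
    measure_profile(extract_profile(mesh, pl), margin_fraction, plateau_level)
  }))
}

#' Measure every endplate of a cohort
#'
#' Maps [measure_endplate()] over a cohort tibble (as produced by
#' [generate_cohort()] or [read_cohort()]). Endplates whose sections fail
#' are reported in the `failures` attribute rather than aborting the run;
#' an error is raised only if every endplate fails.
#'
#' @param cohort tibble with columns `patient`, `sex`, `segment` and a
#'   `mesh` list-column (true-label columns, if present, are carried
#'   through with the matching plane).
#' @inheritParams measure_profile
#' @return A tibble with one row per endplate x plane: identifiers,
#'   metrics columns, and `true_class` / `true_depth` when available.
#' @export
measure_cohort <- function(cohort, margin_fraction = 0.15, plateau_level = 0.9) {
  stopifnot(is.data.frame(cohort), "mesh" %in% names(cohort))
  rows <- vector("list", nrow(cohort))
  fails <- list()
  for (i in seq_len(nrow(cohort))) {
    res <- tryCatch(
      measure_endplate(cohort$mesh[[i]], margin_fraction, plateau_level),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble(
        patient = cohort$patient[i], segment = cohort$segment[i],
        message = conditionMessage(res))
      next
    }
    res$patient <- cohort$patient[i]
    res$sex <- cohort$sex[i] %||% NA_character_
    res$segment <- cohort$segment[i]
    if ("true_class_sagittal" %in% names(cohort)) {
      res$true_class <- ifelse(res$plane == "sagittal",
                               cohort$true_class_sagittal[i],
                               cohort$true_class_coronal[i])
      res$true_depth <- ifelse(res$plane == "sagittal",
                               cohort$true_depth_sagittal[i],
                               cohort$true_depth_coronal[i])
    }
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    stopf("all %d endplates failed to measure; first error: %s",
          nrow(cohort), fails[[1]]$message, class = "epmorph_pipeline_error")
  }
  out <- dplyr::relocate(out, "patient", "sex", "segment", "plane")
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}
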