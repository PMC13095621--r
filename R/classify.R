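#' Classifier thresholds
#'
#' The four-type morphological classification is driven by three
#' thresholds: the concavity-depth cut separating flat from concave
#' endplates (1 mm), the margin-length ratio separating asymmetric from
#' uniform depressions (1.3), and the plateau-fraction cut that
#' operationalises a "flat-bottomed" depression (0.30 of the chord at
#' >= 90% of maximum depth; this last value is a package convention, as
#' the flat-bottom archetype has no published numeric criterion).
#'
#' @param depth_threshold mm; depths below it are flat.
#' @param ratio_threshold dimensionless, > 1.
#' @param plateau_threshold fraction of the chord span.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(depth_threshold = 1.0,
                              ratio_threshold = 1.3,
                              plateau_threshold = 0.30) {
  if (depth_threshold <= 0 || plateau_threshold <= 0 || ratio_threshold <= 1) {
    stopf("thresholds must be positive and ratio_threshold > 1",
          class = "epmorph_parameter_error")
  }
  structure(list(depth_threshold = depth_threshold,
                 ratio_threshold = ratio_threshold,
                 plateau_threshold = plateau_threshold),
            class = "classifier_config")
}

#' Classify measured profiles into the four morphological types
#'
#' Applies the rule set to each row of a metrics table (from
#' [measure_profile()] or [measure_cohort()]), in fixed order:
#'
#' 1. `concavity_depth < depth_threshold` — `flat`;
#' 2. `plateau_fraction >= plateau_threshold` — `flat_bottom`;
#' 3. `ratio >= ratio_threshold` — `asymmetric_concave`;
#' 4. otherwise — `uniform_concave`.
#'
#' Boundary behaviour follows the published rules: a depth of exactly
#' 1 mm is concave and a ratio of exactly 1.3 is asymmetric. The
#' flat-bottom rule precedes the ratio rule because a plateau profile
#' can carry any ratio. The rules partition the metric space, so every
#' finite metrics row receives exactly one class.
#'
#' @param metrics data frame with numeric columns `concavity_depth`,
#'   `ratio`, `plateau_fraction`.
#' @param config a [classifier_config()].
#' @return `metrics` with a `shape_class` factor column appended.
#' @examples
#' classify_shape(tibble::tibble(concavity_depth = c(0.5, 1.5, 1.5),
#'                               ratio = c(1, 1.5, 1.1),
#'                               plateau_fraction = 0.1))$shape_class
#' @export
classify_shape <- function(metrics, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  need <- c("concavity_depth", "ratio", "plateau_fraction")
  if (!all(need %in% names(metrics))) {
    stopf("metrics must have columns %s", paste(need, collapse = ", "),
          class = "epmorph_input_error")
  }
  d <- metrics$concavity_depth
  r <- metrics$ratio
  p <- metrics$plateau_fraction
  if (!all(is.finite(d)) || !all(is.finite(r)) || !all(is.finite(p))) {
    stopf("metrics must be finite", class = "epmorph_input_error")
  }
  cls <- dplyr::case_when(
    d < config$depth_threshold ~ "flat",
    p >= config$plateau_threshold ~ "flat_bottom",
    r >= config$ratio_threshold ~ "asymmetric_concave",
    TRUE ~ "uniform_concave")
  dplyr::mutate(as_tibble(metrics),
                shape_class = factor(cls, levels = shape_levels()))
}

#' Per-segment distribution of morphological types
#'
#' Tabulates classified endplates into the segment-by-type count and
#' percentage layout used for cohort reporting, with a cohort-total row
#' per class appended (`segment == "cohort"`). Percentages sum to 100
#' within each segment.
#'
#' @param classified data frame with columns `segment` and `shape_class`
#'   (optionally `plane`; supply `plane` to filter).
#' @param plane optional plane filter.
#' @return A tibble with columns `segment`, `shape_class`, `n`, `pct`.
#' @export
class_distribution <- function(classified, plane = NULL) {
  stopifnot(all(c("segment", "shape_class") %in% names(classified)))
  if (!is.null(plane) && "plane" %in% names(classified)) {
    classified <- classified[classified$plane == plane, ]
  }
  bad <- setdiff(unique(classified$segment), segment_levels())
  if (length(bad)) {
    stopf("unknown segment label(s): %s", paste(bad, collapse = ", "),
          class = "epmorph_input_error")
  }
  df <- tibble(
    segment = factor(classified$segment, levels = segment_levels()),
    shape_class = factor(classified$shape_class, levels = shape_levels()))
  counts <- as.data.frame(table(df$segment, df$shape_class),
                          responseName = "n", stringsAsFactors = FALSE)
  names(counts)[1:2] <- c("segment", "shape_class")
  counts <- as_tibble(counts)
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$segment),
                          pct = 100 * .data$n / sum(.data$n))
  counts <- dplyr::ungroup(counts)
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$shape_class),
                             n = sum(.data$n), .groups = "drop")
  totals$segment <- "cohort"
  totals$pct <- 100 * totals$n / sum(totals$n)
  out <- dplyr::bind_rows(counts, totals[, c("segment", "shape_class", "n", "pct")])
  out$shape_class <- factor(out$shape_class, levels = shape_levels())
  out
}

#' Aggregate a per-segment count table into cohort totals
#'
#' Takes a wide per-segment count table (columns `segment` plus one count
#' column per shape class, as in [reference_distribution()]) and returns
#' cohort-level totals and percentages per class — e.g. the overall
#' fraction of uniformly concave sagittal endplates.
#'
#' @param counts wide count table for one plane.
#' @return A tibble with `shape_class`, `n`, `total`, `pct`.
#' @examples
#' aggregate_distribution(reference_distribution("sagittal"))
#' @export
aggregate_distribution <- function(counts) {
  cls <- intersect(shape_levels(), names(counts))
  if (!length(cls)) stopf("no shape-class count columns found",
                          class = "epmorph_input_error")
  n <- vapply(counts[cls], sum, numeric(1))
  total <- sum(n)
  tibble(shape_class = factor(cls, levels = shape_levels()),
         n = as.numeric(n), total = total, pct = 100 * n / total)
}
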