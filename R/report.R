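#' Sex-comparison tests for morphology counts
#'
#' Runs the Freeman–Halton exact test and Cramér's V on each
#' segment-by-plane sex-by-type contingency table. Accepts either a long
#' per-endplate classification table (columns `plane`, `segment`, `sex`,
#' `shape_class`) or a wide count table in the layout of
#' [reference_morphology_by_sex()].
#'
#' @param x classification data or wide counts.
#' @return A tibble: `plane`, `segment`, `p_exact`, `chi2`, `cramers_v`.
#' @examples
#' sex_morphology_tests(reference_morphology_by_sex("sagittal"))
#' @export
sex_morphology_tests <- function(x) {
  x <- as_tibble(x)
  cls <- shape_levels()
  if (!all(cls %in% names(x))) {
    if (!all(c("sex", "shape_class") %in% names(x))) {
      stopf("need either wide class-count columns or sex + shape_class",
            class = "epmorph_input_error")
    }
    x <- tidyr::pivot_wider(
      dplyr::count(x, .data$plane, .data$segment, .data$sex, .data$shape_class),
      names_from = "shape_class", values_from = "n", values_fill = 0L)
    for (cl in setdiff(cls, names(x))) x[[cl]] <- 0L
  }
  purrr::map_dfr(split(x, list(x$plane, x$segment), drop = TRUE), function(g) {
    m <- as.matrix(g[, cls])
    fh <- freeman_halton_exact(m)
    tibble(plane = g$plane[1], segment = g$segment[1],
           p_exact = fh$p_exact, chi2 = fh$chi2, cramers_v = fh$cramers_v)
  })
}

#' Sex-comparison t-tests for concavity depth
#'
#' Pooled two-sample t-tests (with CI and Cohen's d) per segment and
#' plane. Accepts either a per-endplate metrics table (columns `plane`,
#' `segment`, `sex`, `concavity_depth`) or a wide summary table in the
#' layout of [reference_depth_by_sex()].
#'
#' @param x metrics data or wide summaries.
#' @return A tibble with group summaries and test columns `t`, `df`,
#'   `p`, `ci_low`, `ci_high`, `cohens_d`.
#' @examples
#' sex_depth_tests(reference_depth_by_sex("sagittal"))
#' @export
sex_depth_tests <- function(x) {
  x <- as_tibble(x)
  if (!all(c("n_male", "mean_male", "sd_male") %in% names(x))) {
    if (!all(c("sex", "concavity_depth") %in% names(x))) {
      stopf("need either wide summary columns or sex + concavity_depth",
            class = "epmorph_input_error")
    }
    x <- tidyr::pivot_wider(
      dplyr::summarise(dplyr::group_by(x, .data$plane, .data$segment, .data$sex),
                       n = dplyr::n(), mean = mean(.data$concavity_depth),
                       sd = sd(.data$concavity_depth), .groups = "drop"),
      names_from = "sex", values_from = c("n", "mean", "sd"))
    for (col in c("n_male", "n_female")) if (!col %in% names(x)) x[[col]] <- 0L
    # a pooled test needs at least two observations per group
    x <- x[!is.na(x$n_male) & !is.na(x$n_female) & x$n_male >= 2 & x$n_female >= 2, ]
    if (!nrow(x)) return(tibble())
  }
  purrr::pmap_dfr(
    x[, c("plane", "segment", "n_male", "mean_male", "sd_male",
          "n_female", "mean_female", "sd_female")],
    function(plane, segment, n_male, mean_male, sd_male,
             n_female, mean_female, sd_female) {
      fit <- pooled_t_test(group_summary(n_male, mean_male, sd_male),
                           group_summary(n_female, mean_female, sd_female))
      tibble(plane = plane, segment = segment,
             n_male = n_male, mean_male = mean_male, sd_male = sd_male,
             n_female = n_female, mean_female = mean_female, sd_female = sd_female,
             t = fit$t, df = fit$df, p = fit$p,
             ci_low = fit$ci_low, ci_high = fit$ci_high, cohens_d = fit$cohens_d)
    })
}

#' Run the full cohort pipeline
#'
#' Generation (or ingestion) → profile extraction → morphometry →
#' classification → cohort statistics, returning a `cohort_report` and
#' optionally writing CSV/JSON outputs. Three input modes:
#'
#' * synthetic (default): a seeded synthetic cohort via
#'   [generate_cohort()];
#' * STL directory: `input` names a directory with `manifest.csv` and
#'   STL meshes (see [write_cohort()]);
#' * stats-only: `input` is a named list with elements `morphology`
#'   and/or `depth`, each a CSV path in the layout of the reference
#'   tables — only the sex-comparison statistics are computed.
#'
#' @param input `NULL`, a directory path, or a named list of CSV paths.
#' @param out_dir output directory; `NULL` writes nothing.
#' @param n_patients synthetic-mode cohort size.
#' @param seed integer seed controlling generation, reliability sampling.
#' @param frame [anatomical_frame()] for STL ingestion.
#' @param config [classifier_config()].
#' @param noise_sd,resolution synthetic-mode surface controls.
#' @param reliability run the [reliability_protocol()] (mesh modes only).
#' @return A list of class `cohort_report`: `metrics`, `classes`,
#'   `distribution`, `sex_morphology`, `sex_depth`, `reliability`,
#'   `failures`, `meta`.
#' @export
run_pipeline <- function(input = NULL, out_dir = NULL,
                         n_patients = 33, seed = 1L,
                         frame = anatomical_frame(),
                         config = classifier_config(),
                         noise_sd = 0.05, resolution = 48,
                         reliability = TRUE) {
  meta <- list(seed = seed, n_patients = n_patients,
               config = unclass(config),
               frame = list(lateral = frame$lateral, ap = frame$ap, si = frame$si),
               package_version = as.character(utils::packageVersion("epmorph")))

  if (is.list(input) && !is.data.frame(input)) {
    report <- stats_only_report(input, meta)
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }

  cohort <- if (is.null(input)) {
    generate_cohort(n_patients = n_patients, seed = seed,
                    noise_sd = noise_sd, resolution = resolution)
  } else if (is.character(input)) {
    read_cohort(input, frame = frame)
  } else {
    stopifnot(is.data.frame(input), "mesh" %in% names(input))
    input
  }

  metrics <- measure_cohort(cohort)
  classes <- classify_shape(metrics, config)
  distribution <- dplyr::bind_rows(
    dplyr::mutate(class_distribution(classes, "sagittal"), plane = "sagittal"),
    dplyr::mutate(class_distribution(classes, "coronal"), plane = "coronal"))
  sexed <- !all(is.na(classes$sex))
  sex_morph <- if (sexed) sex_morphology_tests(classes) else NULL
  sex_depth <- if (sexed) sex_depth_tests(classes) else NULL
  rel <- if (reliability && length(unique(cohort$patient)) >= 10) {
    reliability_protocol(cohort, seed = seed)
  } else NULL

  report <- structure(
    list(metrics = metrics, classes = classes, distribution = distribution,
         sex_morphology = sex_morph, sex_depth = sex_depth,
         reliability = rel, failures = attr(metrics, "failures"),
         meta = meta),
    class = "cohort_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

stats_only_report <- function(input, meta) {
  sm <- sdp <- NULL
  if (!is.null(input$morphology)) {
    sm <- sex_morphology_tests(readr::read_csv(input$morphology, show_col_types = FALSE))
  }
  if (!is.null(input$depth)) {
    sdp <- sex_depth_tests(readr::read_csv(input$depth, show_col_types = FALSE))
  }
  if (is.null(sm) && is.null(sdp)) {
    stopf("stats-only input needs 'morphology' and/or 'depth' CSV paths",
          class = "epmorph_parameter_error")
  }
  structure(list(metrics = NULL, classes = NULL, distribution = NULL,
                 sex_morphology = sm, sex_depth = sdp, reliability = NULL,
                 failures = NULL, meta = meta),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  %d endplate-plane measurements, %d patients\n",
                nrow(x$metrics), length(unique(x$metrics$patient))))
  }
  for (nm in c("distribution", "sex_morphology", "sex_depth", "reliability")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  if (!is.null(x$failures) && nrow(x$failures)) {
    cat(sprintf("  failures: %d endplate(s)\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Writes `metrics.csv`, `classes.csv`, one CSV per summary table under
#' `tables/`, and a single `report.json` bundling everything with the
#' run metadata.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$metrics)) {
    readr::write_csv(report$metrics, file.path(out_dir, "metrics.csv"))
  }
  if (!is.null(report$classes)) {
    readr::write_csv(report$classes, file.path(out_dir, "classes.csv"))
  }
  for (nm in c("distribution", "sex_morphology", "sex_depth", "reliability")) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(out_dir, "tables", paste0(nm, ".csv")))
    }
  }
  json <- report[!vapply(report, is.null, logical(1))]
  json$metrics <- NULL   # bulky; already in metrics.csv
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
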