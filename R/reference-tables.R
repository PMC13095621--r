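#' Reference cohort summary tables
#'
#' Published summary tables from a 3D-CT morphometric study of the L4-S1
#' endplates in 33 healthy young adults (19 male, 14 female; 165
#' endplates), shipped as plain CSV under `inst/extdata/`. They serve two
#' roles: as the default study conditions for [generate_cohort()], and as
#' direct inputs to the statistics layer so the cohort-level analyses can
#' be recomputed from printed summaries.
#'
#' * `reference_distribution()`: per-segment counts of the four
#'   morphological types, by plane.
#' * `reference_morphology_by_sex()`: per-segment sex-by-type contingency
#'   counts with the published exact-test p and Cramér's V.
#' * `reference_depth_by_sex()`: per-segment maximum concavity depth
#'   summaries (n, mean, SD in mm) by sex with the published CI, t, p and
#'   Cohen's d.
#'
#' Columns ending in `_printed` are the published values at their printed
#' precision; all other columns are inputs.
#'
#' @param plane `"sagittal"`, `"coronal"`, or `NULL` for both.
#' @return A tibble.
#' @examples
#' reference_distribution("sagittal")
#' @name reference_tables
NULL

read_reference <- function(file, plane = NULL) {
  path <- system.file("extdata", file, package = "epmorph", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(plane)) {
    plane <- match.arg(plane, c("sagittal", "coronal"))
    df <- df[df$plane == plane, ]
  }
  df
}

#' @rdname reference_tables
#' @export
reference_distribution <- function(plane = NULL) {
  read_reference("reference_distribution.csv", plane)
}

#' @rdname reference_tables
#' @export
reference_morphology_by_sex <- function(plane = NULL) {
  read_reference("reference_morphology_by_sex.csv", plane)
}

#' @rdname reference_tables
#' @export
reference_depth_by_sex <- function(plane = NULL) {
  read_reference("reference_depth_by_sex.csv", plane)
}
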