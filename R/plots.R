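#' Plot an endplate profile with its measurement construction
#'
#' Draws the profile polyline, the measurement chord between the margin
#' points, and the apex (deepest point) with its perpendicular drop.
#'
#' @param object an `endplate_profile`.
#' @param margin_fraction,plateau_level passed to [measure_profile()].
#' @param ... ignored.
#' @return A ggplot.
#' @examples
#' p <- generate_profile(endplate_spec(depth_sagittal = 2.5,
#'                                     apex_offset_sagittal = -0.15,
#'                                     shape_class_sagittal = "asymmetric_concave"),
#'                       "sagittal")
#' ggplot2::autoplot(p)
#' @export
autoplot.endplate_profile <- function(object, margin_fraction = 0.15,
                                      plateau_level = 0.9, ...) {
  m <- measure_profile(object, margin_fraction, plateau_level)
  lab <- attr(object, "end_labels")
  chord <- tibble(s = c(m$margin1_s, m$margin2_s), h = c(m$margin1_h, m$margin2_h))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$h)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_line(data = chord, colour = "steelblue", linetype = 2) +
    ggplot2::geom_point(data = chord, colour = "steelblue", size = 2) +
    ggplot2::annotate("point", x = m$apex_s, y = m$apex_h,
                      colour = "firebrick", size = 2) +
    ggplot2::labs(
      x = sprintf("s (mm), %s → %s", lab[1], lab[2]),
      y = "h (mm, superior)",
      title = sprintf("%s profile: chord %.1f mm, depth %.2f mm, ratio %.2f",
                      profile_plane(object), m$chord_length,
                      m$concavity_depth, m$ratio)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a per-segment shape-class distribution
#'
#' Stacked percentage bars per segment from a [class_distribution()]
#' table (the cohort-total rows are dropped).
#'
#' @param distribution output of [class_distribution()], optionally with
#'   a `plane` column for faceting.
#' @return A ggplot.
#' @export
plot_class_distribution <- function(distribution) {
  df <- distribution[distribution$segment != "cohort", ]
  df$segment <- factor(df$segment, levels = segment_levels())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$pct,
                                        fill = .data$shape_class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", name = "type") +
    ggplot2::labs(x = NULL, y = "% of endplates") +
    ggplot2::theme_minimal()
  if ("plane" %in% names(df)) p <- p + ggplot2::facet_wrap(~plane)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
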