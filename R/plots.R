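# ggplot2 views of the stage outputs.

#' Stacked composition bars per dataset
#'
#' @param composition Output of [composition_table()] (optionally with a
#'   `variable` column from the pipeline).
#' @return A ggplot.
#' @export
plot_composition <- function(composition) {
  dat <- filter(composition, !is.na(.data$category))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dataset, y = .data$proportion,
                                    fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    { if ("variable" %in% names(dat)) ggplot2::facet_wrap(~variable) } +
    ggplot2::labs(x = "dataset", y = "proportion of known values",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of range overlap or area added across taxa
#'
#' @param ranges Output of [range_overlap_added()] or
#'   [lat_range_metrics()].
#' @param metric Column to plot (default `"added_pct"`).
#' @return A ggplot.
#' @export
plot_range_overlap <- function(ranges, metric = "added_pct") {
  ggplot2::ggplot(ranges, ggplot2::aes(x = .data$subset,
                                       y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = "dataset", y = metric) +
    ggplot2::theme_minimal()
}

#' Diversity-through-time curves
#'
#' Raw richness (solid) per dataset, or coverage-standardised richness
#' faceted by quorum when given a [diversity_at_quorum()] table.
#'
#' @param diversity Output of [raw_diversity()] or [diversity_at_quorum()].
#' @return A ggplot.
#' @export
plot_diversity <- function(diversity) {
  if ("quorum" %in% names(diversity)) {
    dat <- filter(diversity, !is.na(.data$richness))
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$richness,
                                      colour = .data$dataset,
                                      group = .data$dataset)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~quorum, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "bin", y = "coverage-standardised richness") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
  } else {
    ggplot2::ggplot(diversity,
                    ggplot2::aes(x = -.data$bin_midpoint, y = .data$richness,
                                 colour = .data$dataset)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "age (Ma, increasing right)", y = "raw richness") +
      ggplot2::theme_minimal()
  }
}

#' Violin plot of within-range occurrence positions
#'
#' @param positions Output of [occurrence_positions()]; position 0 is the
#'   oldest end of the taxon's range.
#' @return A ggplot.
#' @export
plot_positions <- function(positions) {
  ggplot2::ggplot(positions, ggplot2::aes(x = .data$subset,
                                          y = .data$position)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3) +
    ggplot2::labs(x = "dataset",
                  y = "relative position in taxon range (0 = oldest)") +
    ggplot2::theme_minimal()
}

#' Substrate-affinity trajectories per family
#'
#' @param affinity Output of [substrate_affinity()].
#' @return A ggplot.
#' @export
plot_affinity <- function(affinity) {
  dat <- filter(affinity, !is.na(.data$sra))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$sra,
                                    colour = .data$dataset,
                                    group = .data$dataset)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "interval", y = "standardized relative affinity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  }
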