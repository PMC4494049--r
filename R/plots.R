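# ggplot2 views of the main result types.

#' Plot annotation category composition
#'
#' Fraction of queries per annotation category (the stacked accounting
#' usually shown as per-species pie charts).
#'
#' @param annotations Tibble from [annotate_iterative()], optionally with
#'   a `dataset` column for faceting.
#' @return A ggplot object.
#' @export
plot_annotation_categories <- function(annotations) {
  df <- annotations
  df$category <- factor(df$category, levels = ALL_CATEGORIES)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = "", fill = .data$category)) +
    ggplot2::geom_bar(position = "fill", width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "queries", fill = "category") +
    ggplot2::theme_minimal()
  if ("dataset" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$dataset))
  }
  p
}

#' Plot per-region gap fractions of one-to-many consensuses
#'
#' Shows the 5'/middle/3' gap split (30/40/30) used to assess positional
#' coverage bias.
#'
#' @param x A `saurannot_consensus_set` or its [tidy()] stats tibble.
#' @return A ggplot object.
#' @export
plot_coverage_regions <- function(x) {
  stats <- if (inherits(x, "saurannot_consensus_set")) {
    tidy.saurannot_consensus_set(x)
  } else x
  stats <- stats[stats$kind == "one_to_many", , drop = FALSE]
  long <- tidyr::pivot_longer(stats, c("gap5", "gap_mid", "gap3"),
                              names_to = "region", values_to = "gap")
  long$region <- factor(long$region, levels = c("gap5", "gap_mid", "gap3"),
                        labels = c("5' 30%", "middle 40%", "3' 30%"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$gap)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "gap fraction") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_coverage_regions autoplot method for consensus sets.
#' @param object A `saurannot_consensus_set`.
#' @param ... Unused.
#' @export
autoplot.saurannot_consensus_set <- function(object, ...) {
  plot_coverage_regions(object)
}

#' Plot completeness reports
#'
#' Bars of the fraction of each reference set recovered, annotated with
#' the mean aligned coverage.
#'
#' @param reports One `saurannot_completeness` object, a list of them, or
#'   a bound tibble of their `report` rows.
#' @return A ggplot object.
#' @export
plot_completeness <- function(reports) {
  df <- if (inherits(reports, "saurannot_completeness")) {
    reports$report
  } else if (is.data.frame(reports)) {
    reports
  } else {
    dplyr::bind_rows(lapply(reports, function(r) r$report))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_set,
                                   y = .data$fraction_found)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("cov %.0f%%", 100 * .data$mean_coverage)),
      vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05),
                                labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "references found") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_completeness autoplot method.
#' @param object A `saurannot_completeness` object.
#' @param ... Unused.
#' @export
autoplot.saurannot_completeness <- function(object, ...) {
  plot_completeness(object)
}
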