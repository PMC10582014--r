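# ggplot2 views of the main result types.

#' Plot a viral / non-viral split report
#'
#' Stacked read-pair fractions per sample, the bar-chart view of the
#' non-viral to viral ratio.
#'
#' @param x One or more `pedna_split` reports (row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_split <- function(x, ...) {
  d <- as_tibble(x) %>%
    tidyr::pivot_longer(c("n_pairs_viral", "n_pairs_nonviral"),
                        names_to = "fraction", values_to = "pairs") %>%
    mutate(fraction = ifelse(.data$fraction == "n_pairs_viral",
                             "viral", "non-viral"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$pairs,
                                  fill = .data$fraction)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "mapped read pairs",
                  fill = NULL, title = "non-viral vs viral peDNA") +
    ggplot2::theme_minimal()
}

#' @rdname plot_split
#' @param object A `pedna_split` report.
#' @method autoplot pedna_split
#' @export
autoplot.pedna_split <- function(object, ...) plot_split(object, ...)

#' Plot a coverage profile
#'
#' Windowed depth along the MAG with the background level and, optionally,
#' candidate proviral regions highlighted.
#'
#' @param object A `pedna_coverage` from [coverage_profile()].
#' @param regions Optional tibble (`start`, `end`) of regions to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pedna_coverage
#' @export
autoplot.pedna_coverage <- function(object, regions = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$depth)) +
    ggplot2::geom_step(colour = "grey25")
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = regions$start,
                               xmax = regions$end, ymin = -Inf, ymax = Inf,
                               alpha = 0.2, fill = "goldenrod")
  }
  p + ggplot2::geom_hline(yintercept = attr(object, "background"),
                          linetype = 2, colour = "steelblue") +
    ggplot2::labs(x = "position (bp)", y = "mean depth",
                  title = object$mag_id[1]) +
    ggplot2::theme_minimal()
}

#' Plot mechanism assignment counts
#'
#' @param object A `pedna_mechanism` from [call_mechanisms()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pedna_mechanism
#' @export
autoplot.pedna_mechanism <- function(object, ...) {
  d <- count(as_tibble(object), .data$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "MAGs",
                  title = "predominant DNA-export mechanism") +
    ggplot2::theme_minimal()
}

#' Plot signed COG fold changes
#'
#' Bars per category; high-coverage-enriched categories (fold change above
#' 1) point up, depleted ones down; the excluded interval (-1, 1) is shaded.
#'
#' @param object A `pedna_cog_profile` from [fold_changes()] (several may be
#'   row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pedna_cog_profile
#' @export
autoplot.pedna_cog_profile <- function(object, ...) {
  d <- filter(as_tibble(object), !is.na(.data$fold_change))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$fold_change,
                                  fill = .data$fold_change > 1)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -1, ymax = 1,
                      fill = "white", colour = NA) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "COG category", y = "fold change vs metagenome") +
    ggplot2::theme_minimal()
}
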