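# ggplot2 views of the main result types: replicate-distance ECDF and
# histogram, peak-to-TSC distance histograms against the null, enrichment
# tables, and a simple information-content motif logo.

#' ECDF of nearest-replicate peak distances
#'
#' @param distances tibble from [nearest_replicate_distances()] or a numeric
#'   vector of distances.
#' @param xmax right edge of the x axis (bp).
#' @return a ggplot.
#' @export
plot_distance_ecdf <- function(distances, xmax = 200) {
  d <- if (is.data.frame(distances)) distances$distance else distances
  ggplot2::ggplot(tibble(distance = d),
                  ggplot2::aes(x = .data$distance)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, xmax)) +
    ggplot2::labs(x = "distance to nearest replicate peak (bp)",
                  y = "cumulative fraction of peaks") +
    ggplot2::theme_minimal()
}

#' Histogram of replicate-maxima distances for merged peaks
#'
#' @param merged merged peak tibble from [filter_concordant()].
#' @param binwidth histogram bin width in bp.
#' @return a ggplot.
#' @export
plot_replicate_distances <- function(merged, binwidth = 2) {
  ggplot2::ggplot(merged, ggplot2::aes(x = .data$replicate_distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "|replicate maxima difference| (bp)",
                  y = "merged peaks") +
    ggplot2::theme_minimal()
}

#' Peak-to-TSC distance histogram, observed vs randomized
#'
#' @param annotations tibble from [annotate_all()].
#' @param null optional `null_comparison`; its first replicate's distances
#'   are overlaid.
#' @param binwidth bin width in bp.
#' @param xlim signed distance range shown.
#' @return a ggplot.
#' @export
plot_tsc_distances <- function(annotations, null = NULL, binwidth = 50,
                               xlim = c(-2000, 2000)) {
  df <- tibble(distance = annotations$nearest_gene_distance,
               set = "observed")
  if (!is.null(null)) {
    df <- bind_rows(df, tibble(distance = null$distance_samples,
                               set = "random"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                   fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "signed distance to nearest predicted TSC (bp)",
                  y = "sites", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Enrichment table dot plot
#'
#' Observed versus expected gene counts per category or list, sized by
#' -log10 p.
#'
#' @param enrichment tibble from [category_table()] or rows from
#'   [genelist_enrichment()].
#' @return a ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  df <- filter(enrichment, .data$label != "Total", !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_expected_raw,
                                   y = .data$n_observed,
                                   size = -log10(pmax(.data$p_value,
                                                      1e-16)))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8,
                       vjust = -1, check_overlap = TRUE,
                       show.legend = FALSE) +
    ggplot2::labs(x = "expected genes", y = "observed genes",
                  size = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Information-content motif logo
#'
#' Stacked letters per column; letter height is the column information
#' content (bits) split by base frequency, as in standard sequence logos.
#'
#' @param x a `motif` object.
#' @param object,... autoplot method arguments.
#' @return a ggplot.
#' @export
plot_motif_logo <- function(x) {
  td <- tidy(x)
  df <- td %>%
    mutate(height = .data$probability * .data$ic) %>%
    group_by(.data$position) %>%
    arrange(.data$height, .by_group = TRUE) %>%
    mutate(ymax = cumsum(.data$height),
           ymin = .data$ymax - .data$height) %>%
    ungroup() %>%
    filter(.data$height > 0.01)
  base_cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B",
                 T = "#D62839")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$position - 0.45,
                                    xmax = .data$position + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$base),
                       alpha = 0.25) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$position, y = (.data$ymin + .data$ymax) / 2,
      label = .data$base, colour = .data$base,
      size = .data$height), fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(1.5, 8)) +
    ggplot2::scale_fill_manual(values = base_cols, guide = "none") +
    ggplot2::scale_colour_manual(values = base_cols) +
    ggplot2::scale_x_continuous(breaks = seq_len(x$width)) +
    ggplot2::labs(x = "motif position", y = "information content (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' @rdname plot_motif_logo
#' @importFrom ggplot2 autoplot
#' @method autoplot motif
#' @export
autoplot.motif <- function(object, ...) plot_motif_logo(object)

#' @export
ggplot2::autoplot
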