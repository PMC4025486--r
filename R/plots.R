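# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a single-nucleotide profile
#'
#' @param object A `nucleotide_profile` from [nucleotide_profile()].
#' @param ... Unused.
#' @return A ggplot: per-position base frequencies around the poly(A) site.
#' @method autoplot nucleotide_profile
#' @export
autoplot.nucleotide_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("A", "C", "G", "U"),
                              names_to = "base", values_to = "freq")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$freq,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = -1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to poly(A) site",
                  y = "base frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked motifs of a scan
#'
#' @param object A `motif_table` from [scan_kmers()].
#' @param n Number of top motifs to show.
#' @param ... Unused.
#' @return A ggplot bar chart of motif frequencies (fill mapped to Z-score
#'   when present).
#' @method autoplot motif_table
#' @export
autoplot.motif_table <- function(object, n = 15L, ...) {
  top <- utils::head(arrange(as_tibble(object), .data$rank), n)
  p <- ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$kmer, -.data$freq), y = .data$freq))
  p <- if ("zscore" %in% names(top)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$zscore)) +
      ggplot2::scale_fill_viridis_c(name = "Z")
  } else p + ggplot2::geom_col(fill = "steelblue")
  p + ggplot2::labs(x = NULL, y = "frequency per sequence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of the regional distribution of PACs
#'
#' @param region_summary Tibble from [region_distribution()].
#' @return A ggplot.
#' @export
plot_region_distribution <- function(region_summary) {
  ggplot2::ggplot(region_summary,
                  ggplot2::aes(x = .data$region, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of PACs") +
    ggplot2::theme_minimal()
}

#' Boxplot of feature lengths with and without PACs
#'
#' @param with_pac Numeric lengths of features containing a PAC.
#' @param controls Tibble from [sample_controls()] (`length`, `group`).
#' @return A ggplot on a log10 length scale.
#' @export
plot_length_comparison <- function(with_pac, controls) {
  if (is.data.frame(with_pac)) with_pac <- with_pac$length
  df <- bind_rows(tibble(group = "PA", length = with_pac),
                  select(controls, "group", "length"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$length)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "length (nt)") +
    ggplot2::theme_minimal()
}
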