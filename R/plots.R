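#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segment profile
#'
#' Draws the minimum non-overlapping exon units of a gene as blocks whose
#' height is the isoform inclusion count, with gap segments at zero —
#' a visual rendering of the gene's count string.
#'
#' @param object An `ase_segments` tibble from [flatten_units()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ase_segments
#' @export
autoplot.ase_segments <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = .data$count,
                                    fill = .data$kind),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(unit = "steelblue", gap = "grey85"),
                               name = NULL) +
    ggplot2::labs(x = sprintf("%s (%s strand)", df$chrom[1], df$strand[1]),
                  y = "isoforms covering unit",
                  title = df$gene_id[1],
                  subtitle = paste("count string", count_string(df))) +
    ggplot2::theme_minimal()
}

#' Plot evaluation metrics
#'
#' Bar chart of the rate of known events and recall.
#'
#' @param object An `ase_metrics` object from [compute_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ase_metrics
#' @export
autoplot.ase_metrics <- function(object, ...) {
  df <- tidy(object) |> filter(.data$metric %in% c("rke", "recall"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction",
                  title = sprintf("%d / %d data events known; %d / %d known recovered",
                                  object$n_overlap, object$n_data,
                                  object$n_overlap, object$n_known)) +
    ggplot2::theme_minimal()
}
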