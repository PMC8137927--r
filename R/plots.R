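#' Plot a metagene profile
#'
#' 1-D metagenes are drawn as an rpm trace against the offset from the
#' anchor codon; with `matrix = TRUE` (requires a [metagene_2d()]
#' result) a length-by-offset heat map is drawn instead.
#'
#' @param object A `ribo_metagene`.
#' @param matrix Draw the length-resolved heat map?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ribo_metagene
#' @export
autoplot.ribo_metagene <- function(object, matrix = FALSE, ...) {
  anchor_lab <- sprintf("offset from %s codon (nt)", object$anchor)
  if (matrix) {
    df <- tidy.ribo_metagene(object, matrix = TRUE)
    return(
      ggplot2::ggplot(df, ggplot2::aes(offset, length, fill = mean_rpm)) +
        ggplot2::geom_raster() +
        ggplot2::scale_fill_viridis_c(name = "rpm") +
        ggplot2::labs(x = anchor_lab, y = "footprint length (nt)",
                      title = sprintf("%s ends, %d genes",
                                      sub("_", " ", object$align_end),
                                      object$n_genes)) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$trace, ggplot2::aes(offset, mean_rpm)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = anchor_lab, y = "mean occupancy (rpm)",
                  title = sprintf("%s-anchored metagene (%s ends, %d genes)",
                                  object$anchor, sub("_", " ", object$align_end),
                                  object$n_genes)) +
    ggplot2::theme_minimal()
}

#' @export
plot.ribo_metagene <- function(x, ...) print(autoplot.ribo_metagene(x, ...))

#' Bar chart of footprint region proportions
#'
#' @param rf Tibble from [region_fractions()], optionally with an
#'   extra `sample` column for dodged comparison across samples.
#' @return A ggplot object.
#' @export
plot_region_fractions <- function(rf) {
  p <- ggplot2::ggplot(rf, ggplot2::aes(region, fraction))
  if ("sample" %in% names(rf)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = sample),
                               position = ggplot2::position_dodge())
  } else {
    p <- p + ggplot2::geom_col(fill = "grey35")
  }
  p + ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of footprints") +
    ggplot2::theme_minimal()
}

#' Histogram of footprint lengths
#'
#' @param lh Tibble from [length_histogram()]; faceted by region when
#'   present.
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(lh) {
  p <- ggplot2::ggplot(lh, ggplot2::aes(length, count)) +
    ggplot2::geom_col(width = 0.9, fill = "grey35") +
    ggplot2::labs(x = "footprint length (nt)", y = "footprints") +
    ggplot2::theme_minimal()
  if ("region" %in% names(lh)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(region), scales = "free_y")
  }
  p
}

#' Volcano-style plot of codon bootstrap results
#'
#' Mean mutant/WT stop-peak ratio per codon against bootstrap
#' significance, with significant codons highlighted and the
#' transcriptome mean marked.
#'
#' @param object A `codon_boot` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot codon_boot
#' @export
autoplot.codon_boot <- function(object, ...) {
  df <- tidy.codon_boot(object)
  mu <- attr(object, "transcriptome_mean")
  p <- ggplot2::ggplot(df, ggplot2::aes(mean_ratio, -log10(p_value))) +
    ggplot2::geom_vline(xintercept = mu, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(color = significant), size = 1.5) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey55", `TRUE` = "red3"),
                                guide = "none") +
    ggplot2::labs(x = "mean stop-peak ratio (mutant / WT)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
  if (any(df$significant)) {
    p <- p + ggplot2::geom_text(
      data = df[df$significant, ],
      ggplot2::aes(label = codon), vjust = -0.8, size = 3, color = "red3")
  }
  if (length(unique(df$position)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(position))
  }
  p
}

#' @export
plot.codon_boot <- function(x, ...) print(autoplot.codon_boot(x, ...))
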