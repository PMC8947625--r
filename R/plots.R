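# ggplot2 renderings of the landscape matrices.

#' Plot an oncoplot matrix
#'
#' @param m A matrix from [oncoplot_matrix()].
#' @return A ggplot object (gene x sample tiles colored by consequence
#'   class, columns grouped by cohort group).
#' @export
plot_oncoplot <- function(m) {
  groups <- attr(m, "groups")
  df <- expand.grid(gene = rownames(m), sample_id = colnames(m),
                    stringsAsFactors = FALSE)
  df$consequence <- as.vector(m)
  df$group <- groups[df$sample_id]
  df$gene <- factor(df$gene, levels = rev(rownames(m)))
  df$sample_id <- factor(df$sample_id, levels = colnames(m))
  ggplot2::ggplot(df[!is.na(df$consequence), ],
                  ggplot2::aes(x = .data$sample_id, y = .data$gene,
                               fill = .data$consequence)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group),
                        scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample", y = NULL, fill = "consequence")
}

#' Plot lollipop data for one gene
#'
#' @param lollipop A tibble from [lollipop_data()].
#' @param gene Gene symbol used in the title.
#' @param regions Optional region map (columns `region`, `start`, `end`)
#'   drawn as shaded protein domains.
#' @return A ggplot object.
#' @export
plot_lollipop <- function(lollipop, gene = NULL, regions = NULL) {
  p <- ggplot2::ggplot(lollipop,
                       ggplot2::aes(x = .data$residue,
                                    y = .data$n_occurrences))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(regions),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$residue, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = .data$klass), size = 2.5) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = gene, x = "protein residue",
                  y = "occurrences", color = "class")
}
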