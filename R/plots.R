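#' Workflow figures
#'
#' ggplot2 builders for the standard views of the analysis: PCA
#' ordination, volcano plot, ORA dot plot and the GSEA enrichment
#' profile; igraph renderers for the regulatory-network layouts.
#'
#' @name workflow_plots
NULL

#' @param pca result of [pca_ordination()].
#' @param color,shape metadata columns mapped to aesthetics.
#' @rdname workflow_plots
#' @export
plot_pca <- function(pca, color = "strain", shape = "cell_type") {
  df <- pca$coordinates
  ve <- round(100 * pca$var_explained[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   color = .data[[color]],
                                   shape = .data[[shape]])) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_bw()
}

#' @param de_results data.frame from [wald_test()] with a `class` column.
#' @rdname workflow_plots
#' @export
plot_volcano <- function(de_results) {
  df <- de_results[!is.na(de_results$padj), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$padj),
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "red", down = "darkgreen",
                                           ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}

#' @param ora_results data.frame from [ora_test()].
#' @param top_n sets shown (by adjusted p).
#' @rdname workflow_plots
#' @export
plot_ora_dotplot <- function(ora_results, top_n = 15) {
  df <- utils::head(ora_results[order(ora_results$padj), ], top_n)
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_ratio, .data$set_id,
                                   size = .data$k, color = .data$padj)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "overlap",
                  color = "adjusted p") +
    ggplot2::theme_bw()
}

#' @param ranked ranked list from [rank_genes()].
#' @param set gene-id vector of the displayed set.
#' @param weight running-sum weight exponent.
#' @param title plot title.
#' @rdname workflow_plots
#' @export
plot_gsea_enrichment <- function(ranked, set, weight = 1, title = NULL) {
  es <- enrichment_score(ranked, set, weight)
  n <- nrow(ranked)
  prof <- data.frame(rank = seq_len(n), running = es$running)
  top <- ggplot2::ggplot(prof, ggplot2::aes(.data$rank, .data$running)) +
    ggplot2::geom_line(color = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_rug(data = data.frame(rank = es$hit_index),
                      ggplot2::aes(x = .data$rank), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.06, "npc")) +
    ggplot2::labs(y = "enrichment score", x = NULL,
                  title = title %||% sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_bw()
  bottom <- ggplot2::ggplot(data.frame(rank = seq_len(n), score = ranked$score),
                            ggplot2::aes(.data$rank, .data$score)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::labs(x = "rank in ordered list", y = "rank metric") +
    ggplot2::theme_bw()
  patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(2, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a regulatory subnetwork to PNG
#'
#' Circular layout for the master-regulator overview and a tree layout
#' for refined TF-target subnetworks. TF nodes are orange, regulated
#' genes light blue; edges are coloured red (up target), blue (down) or
#' black (mixed regulation).
#'
#' @param subnetwork a `reg_subnetwork`.
#' @param path output PNG path.
#' @param layout "circle" or "tree".
#' @param width,height,res device settings.
#' @return invisibly, the path.
#' @export
plot_network_png <- function(subnetwork, path, layout = c("circle", "tree"),
                             width = 1600, height = 1600, res = 150) {
  layout <- match.arg(layout)
  g <- subnetwork_to_igraph(subnetwork)
  vcol <- ifelse(igraph::V(g)$kind == "tf", "orange", "lightblue")
  ecls <- igraph::E(g)$regulation_class
  ecol <- ifelse(is.na(ecls), "grey50",
          ifelse(ecls == "up", "red", ifelse(ecls == "down", "blue", "black")))
  lay <- if (layout == "circle") igraph::layout_in_circle(g)
         else igraph::layout_as_tree(g)
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(g, layout = lay, vertex.color = vcol, vertex.size = 6,
       vertex.label.cex = 0.6, edge.color = ecol, edge.arrow.size = 0.3)
  invisible(path)
}
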