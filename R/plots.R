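# Default exports mirror the pipeline's QC figure set. Colors come from a
# colorblind-safe palette (Okabe-Ito, recycled beyond 8 levels).

cb_palette <- function(n) {
  base <- grDevices::palette.colors(palette = "Okabe-Ito")[-1]
  rep_len(unname(base), n)
}

umap_frame <- function(table, assignment = NULL) {
  stopifnot(!is.null(table$cell_meta$umap1))
  df <- table$cell_meta
  if (!is.null(assignment)) df$cluster <- factor(assignment$labels)
  df
}

#' UMAP scatter colored by cluster
#'
#' @param table a `cell_table` with embedding columns.
#' @param assignment a `cluster_assignment`.
#' @param split_by optional metadata column to facet by (e.g. `pool_id` for
#'   a split-by-batch view).
#' @return a ggplot object.
#' @export
plot_embedding <- function(table, assignment, split_by = NULL) {
  df <- umap_frame(table, assignment)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = umap1, y = umap2,
                                        color = cluster)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::scale_color_manual(values = cb_palette(nlevels(df$cluster))) +
    ggplot2::guides(color = ggplot2::guide_legend(
      override.aes = list(size = 2))) +
    ggplot2::labs(x = "UMAP1", y = "UMAP2") +
    ggplot2::theme_bw()
  if (!is.null(split_by)) {
    g <- g + ggplot2::facet_wrap(stats::as.formula(paste("~", split_by)))
  }
  g
}

#' Per-marker feature plot in UMAP space
#'
#' @param table a `cell_table` with embedding columns and `trans_expr`.
#' @param channel channel name to color by (transformed scale).
#' @return a ggplot object.
#' @export
plot_feature <- function(table, channel) {
  df <- umap_frame(table)
  df$value <- table$trans_expr[, channel]
  ggplot2::ggplot(df, ggplot2::aes(x = umap1, y = umap2, color = value)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_color_viridis_c(name = channel) +
    ggplot2::labs(x = "UMAP1", y = "UMAP2", title = channel) +
    ggplot2::theme_bw()
}

# Heatmap exports (file x cluster frequencies, median expression).
save_heatmap <- function(mat, path, main) {
  ok <- apply(mat, 1, function(r) all(is.finite(r)))
  mat <- mat[ok, , drop = FALSE]
  if (nrow(mat) < 2 || ncol(mat) < 2) return(invisible(NULL))
  grDevices::png(path, width = 900, height = 700)
  pheatmap::pheatmap(mat, main = main, cluster_rows = nrow(mat) > 2,
                     cluster_cols = ncol(mat) > 2)
  grDevices::dev.off()
  invisible(path)
}
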