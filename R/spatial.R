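# Spatial follow-up for imaging-derived tables: join cluster labels to
# cell centroids and region annotations, compute per-cluster stroma/tumor
# enrichment, and export overlay tables for image viewers.

#' Per-region cluster composition
#'
#' `freq[c, r]` = cells of cluster c in region r divided by the total cells
#' in region r, so each region column is a probability vector over
#' clusters. Regions with zero cells are dropped with a warning.
#'
#' @param assignment a `cluster_assignment`.
#' @param regions data.frame with columns `cell_id`, `x`, `y`, `region`,
#'   row-aligned with the assignment's cells.
#' @return cluster x region matrix of proportions.
#' @export
region_frequencies <- function(assignment, regions) {
  stopifnot(length(assignment$labels) == nrow(regions))
  cl <- factor(assignment$labels, levels = seq_len(assignment$C))
  rg <- if (is.factor(regions$region)) regions$region
        else factor(regions$region)
  counts <- as.matrix(table(cl, rg))
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("dropping region(s) with zero cells: ",
            paste(colnames(counts)[empty], collapse = ", "), call. = FALSE)
    counts <- counts[, !empty, drop = FALSE]
  }
  freq <- sweep(counts, 2, colSums(counts), "/")
  rownames(freq) <- paste0("cluster_", seq_len(assignment$C))
  freq
}

#' Per-cluster log2 stroma/tumor enrichment
#'
#' `log2(freq[c, stroma] / freq[c, tumor])` per cluster. Clusters with zero
#' frequency in either region are flagged undefined rather than imputed
#' with a pseudocount.
#'
#' @param freq cluster x region matrix from [region_frequencies()], with
#'   `stroma` and `tumor` columns.
#' @param stroma,tumor region column names.
#' @return data.frame with columns `cluster`, `log2fc`, `defined`.
#' @export
log2_enrichment <- function(freq, stroma = "stroma", tumor = "tumor") {
  missing <- setdiff(c(stroma, tumor), colnames(freq))
  if (length(missing)) {
    stop("region column(s) absent from frequency matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fs <- freq[, stroma]; ft <- freq[, tumor]
  defined <- fs > 0 & ft > 0
  data.frame(cluster = seq_len(nrow(freq)),
             log2fc = ifelse(defined, log2(fs / ft), NA_real_),
             defined = defined, row.names = NULL)
}

#' Export a cluster/centroid overlay table
#'
#' CSV of `{cell_id, x, y, cluster}` for integration with segmented images,
#' optionally restricted to a set of clusters (e.g. a single cluster of
#' interest).
#'
#' @param assignment a `cluster_assignment`.
#' @param regions data.frame with `cell_id`, `x`, `y` (and optionally
#'   `region`), row-aligned.
#' @param path output CSV path.
#' @param cluster_filter optional integer set of clusters to keep.
#' @return the overlay data.frame, invisibly.
#' @export
export_overlay <- function(assignment, regions, path,
                           cluster_filter = NULL) {
  stopifnot(length(assignment$labels) == nrow(regions))
  out <- data.frame(cell_id = regions$cell_id, x = regions$x, y = regions$y,
                    cluster = assignment$labels)
  if (!is.null(cluster_filter)) {
    out <- out[out$cluster %in% cluster_filter, , drop = FALSE]
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
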