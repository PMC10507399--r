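# Cluster-level summary matrices: per-file frequencies (raw counts and
# within-file proportions), per-cluster median transformed expression, and
# batch composition. Columns are named cluster_<n> and cover every cluster
# id the backend defines, including empty nodes.

#' Per-file cluster frequency matrices
#'
#' @param table a `cell_table`.
#' @param assignment a `cluster_assignment` aligned to the table.
#' @return list with `freq_raw` (file x cluster counts), `freq_norm`
#'   (within-file proportions; rows sum to 1 for files with >= 1 event) and
#'   `batch_comp` (batch x cluster counts).
#' @export
cluster_frequencies <- function(table, assignment) {
  stopifnot(length(assignment$labels) == n_events(table))
  cl <- factor(assignment$labels, levels = seq_len(assignment$C))
  files <- factor(table$cell_meta$file_name,
                  levels = unique(table$cell_meta$file_name))
  freq_raw <- as.matrix(table(files, cl))
  dimnames(freq_raw) <- list(levels(files),
                             paste0("cluster_", seq_len(assignment$C)))
  rs <- rowSums(freq_raw)
  freq_norm <- freq_raw / ifelse(rs == 0, 1, rs)

  batches <- factor(table$cell_meta$pool_id,
                    levels = unique(table$cell_meta$pool_id))
  batch_comp <- as.matrix(table(batches, cl))
  dimnames(batch_comp) <- list(levels(batches), colnames(freq_raw))
  list(freq_raw = freq_raw, freq_norm = freq_norm, batch_comp = batch_comp)
}

#' Per-cluster median transformed expression
#'
#' Medians of the arcsinh-transformed values per cluster over ALL markers
#' (not only the clustering set), unscaled. Empty clusters yield rows of
#' `NA`. Set `row_scale = TRUE` for the row-scaled heatmap variant
#' ((x - row mean) / row sd, with sd 0 mapped to 0).
#'
#' @param table a `cell_table` with `trans_expr`.
#' @param assignment a `cluster_assignment`.
#' @param markers marker metadata data.frame (defines channel order).
#' @param row_scale return the row-scaled variant.
#' @return cluster x marker matrix with rownames `cluster_<n>`.
#' @export
cluster_median_expression <- function(table, assignment, markers,
                                      row_scale = FALSE) {
  stopifnot(!is.null(table$trans_expr))
  X <- table$trans_expr[, markers$channel_name, drop = FALSE]
  out <- matrix(NA_real_, assignment$C, ncol(X),
                dimnames = list(paste0("cluster_", seq_len(assignment$C)),
                                markers$channel_name))
  for (c in seq_len(assignment$C)) {
    rows <- which(assignment$labels == c)
    if (length(rows)) {
      out[c, ] <- apply(X[rows, , drop = FALSE], 2, median)
    }
  }
  if (row_scale) out <- t(apply(out, 1, scale_row))
  out
}

# (x - mean) / sd with a zero-sd guard: constant rows scale to 0.
scale_row <- function(x) {
  if (all(is.na(x))) return(x)
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Build the full cluster summary
#'
#' Bundles the frequency matrices and median-expression matrix into one
#' `cluster_summary` object.
#'
#' @inheritParams cluster_median_expression
#' @return list of class `cluster_summary` with `freq_raw`, `freq_norm`,
#'   `batch_comp`, `median_expr`, `n_clusters`.
#' @export
summarize_clusters <- function(table, assignment, markers) {
  fr <- cluster_frequencies(table, assignment)
  me <- cluster_median_expression(table, assignment, markers)
  structure(c(fr, list(median_expr = me, n_clusters = assignment$C)),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster_summary: %d clusters, %d files, %d batches\n",
              x$n_clusters, nrow(x$freq_raw), nrow(x$batch_comp)))
  invisible(x)
}

#' Write summary matrices as CSV files
#'
#' @param summary a `cluster_summary`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "cluster_freq_raw.csv"),
             file.path(dir, "cluster_freq_norm.csv"),
             file.path(dir, "batch_composition.csv"),
             file.path(dir, "cluster_median_expression.csv"))
  write.csv(summary$freq_raw, paths[1])
  write.csv(summary$freq_norm, paths[2])
  write.csv(summary$batch_comp, paths[3])
  write.csv(summary$median_expr, paths[4])
  invisible(paths)
}
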