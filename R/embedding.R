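# 2-D neighborhood-preserving embedding (UMAP via uwot) of the transformed
# matrix, restricted to markers flagged used_for_UMAP. The embedding is for
# visualization and QC only; clustering never consumes these coordinates.

#' Compute a 2-D UMAP embedding
#'
#' Runs uwot's UMAP on the transformed expression of the markers flagged
#' `used_for_UMAP`, single-threaded for reproducibility under the supplied
#' seed.
#'
#' @param table a `cell_table` with `trans_expr`.
#' @param markers marker metadata data.frame.
#' @param params list of UMAP parameters: `n_neighbors` (15), `min_dist`
#'   (0.1), `spread` (0.1), `learning_rate` (0.5), `init` ("random"),
#'   `seed`. If `spread < min_dist` the spread is raised to `min_dist` with
#'   a warning (the fitted min_dist/spread curve requires spread >=
#'   min_dist).
#' @return list of class `embedding_result` with `coords` (event x 2 matrix,
#'   columns umap1/umap2) and `params_used`.
#' @export
compute_embedding <- function(table, markers, params = list()) {
  p <- utils::modifyList(default_config()$umap, params)
  X <- marker_matrix(table, markers, "used_for_UMAP")
  if (nrow(X) < p$n_neighbors + 1) {
    stop(sprintf(paste0("embedding needs at least n_neighbors + 1 = %d events",
                        " but only %d are present; reduce n_neighbors"),
                 p$n_neighbors + 1, nrow(X)), call. = FALSE)
  }
  if (p$spread < p$min_dist) {
    warning(sprintf("umap spread (%g) < min_dist (%g); raising spread to %g",
                    p$spread, p$min_dist, p$min_dist), call. = FALSE)
    p$spread <- p$min_dist
  }
  coords <- with_seed(p$seed, {
    uwot::umap(X, n_neighbors = p$n_neighbors, min_dist = p$min_dist,
               spread = p$spread, learning_rate = p$learning_rate,
               init = p$init, n_threads = 1, n_sgd_threads = 0)
  })
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coords = coords, params_used = p),
            class = "embedding_result")
}

#' Attach embedding coordinates to the cell metadata
#'
#' @param table a `cell_table`.
#' @param embedding an `embedding_result` from [compute_embedding()].
#' @return the table with `umap1`/`umap2` metadata columns.
#' @export
add_embedding <- function(table, embedding) {
  stopifnot(nrow(embedding$coords) == n_events(table))
  table$cell_meta$umap1 <- embedding$coords[, 1]
  table$cell_meta$umap2 <- embedding$coords[, 2]
  table
}
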