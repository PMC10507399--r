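# Online self-organizing map clustering on an xdim x ydim grid. Each grid
# node acts as a cluster; nodes may optionally be merged into metaclusters
# by hierarchically clustering the codebook.

#' Train a self-organizing map
#'
#' Online SOM training on an `xdim` x `ydim` grid: the codebook is
#' initialized from a seeded uniform sample of data rows, then updated for
#' `rlen` passes over the data. At each step the best-matching unit (BMU,
#' nearest prototype by Euclidean distance, ties to the lowest node index)
#' and all nodes within the current grid radius (threshold/"bubble"
#' neighborhood) move toward the presented event by the current learning
#' rate. Learning rate and radius both decay linearly; the starting radius
#' is the 0.67 quantile of node-to-node grid distances.
#'
#' @param X event x marker numeric matrix.
#' @param xdim,ydim grid dimensions (>= 1).
#' @param params list overriding training hyperparameters: `rlen` (10
#'   passes), `alpha_start` (0.05), `alpha_end` (0.01), `radius_quantile`
#'   (0.67), `seed`.
#' @return object of class `som_model` with elements `xdim`, `ydim`,
#'   `codebook` ((xdim*ydim) x marker matrix), `grid` (per-node row/col),
#'   `params`.
#' @export
train_som <- function(X, xdim = 6, ydim = 6, params = list()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("SOM input contains non-finite values",
                               call. = FALSE)
  if (nrow(X) < 1 || ncol(X) < 1) stop("SOM input is empty", call. = FALSE)
  stopifnot(xdim >= 1, ydim >= 1)
  p <- utils::modifyList(
    list(rlen = 10L, alpha_start = 0.05, alpha_end = 0.01,
         radius_quantile = 0.67, seed = 42L),
    params)
  m <- xdim * ydim
  if (m > nrow(X)) {
    warning(sprintf("grid has %d nodes but only %d events; some clusters %s",
                    m, nrow(X), "will be empty"), call. = FALSE)
  }
  grid <- expand.grid(col = seq_len(xdim), row = seq_len(ydim))
  gd <- as.matrix(dist(grid[, c("row", "col")]))
  radius_start <- if (m > 1) unname(quantile(gd[upper.tri(gd)],
                                             p$radius_quantile)) else 0

  steps <- with_seed(p$seed, {
    init_idx <- sample.int(nrow(X), m, replace = m > nrow(X))
    order <- as.integer(sample.int(nrow(X), p$rlen * nrow(X),
                                   replace = TRUE)) - 1L
    list(init = init_idx, order = order)
  })
  codebook <- som_train_cpp(X, X[steps$init, , drop = FALSE], steps$order,
                            p$alpha_start, p$alpha_end, radius_start, 0, gd)
  colnames(codebook) <- colnames(X)
  structure(list(xdim = xdim, ydim = ydim, codebook = codebook,
                 grid = grid,
                 params = c(p, list(radius_start = radius_start))),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d grid (%d nodes), %d markers\n",
              x$xdim, x$ydim, nrow(x$codebook), ncol(x$codebook)))
  invisible(x)
}

new_cluster_assignment <- function(labels, C, backend, meta_map = NULL) {
  stopifnot(all(labels >= 1L), all(labels <= C))
  structure(list(labels = as.integer(labels), C = as.integer(C),
                 backend = backend, meta_map = meta_map),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d events, %d clusters (%d occupied)\n",
              x$backend, length(x$labels), x$C, length(unique(x$labels))))
  invisible(x)
}

#' Assign events to their best-matching SOM node
#'
#' Each event is labeled with the index of its nearest codebook prototype
#' (Euclidean distance, ties to the lowest node index). The model defines
#' `xdim * ydim` clusters; nodes may own zero events.
#'
#' @param model a `som_model`.
#' @param X event x marker matrix with the same columns as the codebook.
#' @return a `cluster_assignment` with `C = xdim * ydim`.
#' @export
assign_bmu <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$codebook)) {
    stop(sprintf("column mismatch: data has %d markers, codebook %d",
                 ncol(X), ncol(model$codebook)), call. = FALSE)
  }
  labels <- map_to_codes_cpp(X, model$codebook)
  new_cluster_assignment(labels, nrow(model$codebook), "som")
}

#' Merge SOM nodes into metaclusters
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean) of the
#' codebook rows, cut at `nClus` groups. Deterministic given the codebook.
#'
#' @param model a `som_model`.
#' @param nClus number of metaclusters, between 1 and `xdim * ydim`.
#' @return integer node -> metacluster map of length `xdim * ydim`.
#' @export
metacluster_codes <- function(model, nClus) {
  m <- nrow(model$codebook)
  if (nClus < 1 || nClus > m) {
    stop(sprintf("nClus must be in 1..%d (got %s)", m, nClus), call. = FALSE)
  }
  if (nClus == m) return(seq_len(m))
  hc <- hclust(dist(model$codebook), method = "average")
  unname(cutree(hc, k = nClus))
}

#' Relabel a SOM assignment by its metacluster map
#'
#' @param assignment a `cluster_assignment` from [assign_bmu()].
#' @param meta_map integer node -> metacluster map from
#'   [metacluster_codes()].
#' @return a `cluster_assignment` with backend `"som_meta"`.
#' @export
apply_metaclusters <- function(assignment, meta_map) {
  stopifnot(length(meta_map) == assignment$C)
  new_cluster_assignment(meta_map[assignment$labels], max(meta_map),
                         "som_meta", meta_map = meta_map)
}
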