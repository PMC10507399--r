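# Cluster-resolution optimization: sweep SOM grid sizes, score each
# clustering with the Davies-Bouldin index (lower = better separated),
# and select a grid (manually by default, mirroring the pipeline's
# pause-for-user design; automatic modes for scripted runs).

#' Davies-Bouldin index
#'
#' DBI = (1/K) * sum_i max_{j != i} (S_i + S_j) / M_ij over the K non-empty
#' clusters, where S_i is the mean Euclidean distance of cluster-i events to
#' the cluster-i centroid and M_ij the Euclidean distance between centroids.
#' Empty cluster ids are dropped (a zero-member centroid is undefined).
#'
#' @param X event x feature numeric matrix.
#' @param labels per-event cluster ids (integer-like).
#' @return non-negative scalar; lower values indicate better-separated,
#'   more compact clusters.
#' @export
davies_bouldin_index <- function(X, labels) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  ids <- sort(unique(labels))
  K <- length(ids)
  if (K < 2) stop("DBI undefined: fewer than 2 non-empty clusters",
                  call. = FALSE)
  centroids <- matrix(0, K, ncol(X))
  S <- numeric(K)
  for (i in seq_len(K)) {
    rows <- X[labels == ids[i], , drop = FALSE]
    centroids[i, ] <- colMeans(rows)
    S[i] <- mean(sqrt(rowSums(sweep(rows, 2, centroids[i, ])^2)))
  }
  M <- as.matrix(dist(centroids))
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Default series of SOM grid sizes
#'
#' Reads the packaged `grid_sizes.csv` (columns `xdim`, `ydim`), the default
#' series swept during resolution optimization.
#'
#' @param path optional path to a user grid-sizes CSV.
#' @return data.frame with columns `xdim`, `ydim`.
#' @export
default_grid_sizes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grid_sizes.csv", package = "cytosweep")
  }
  df <- read.csv(path)
  require_columns(df, c("xdim", "ydim"), "grid_sizes")
  df
}

#' Sweep SOM grid sizes and score each with the DBI
#'
#' Trains a SOM and assigns events for every grid in `grid_sizes`, computing
#' the Davies-Bouldin index of each clustering on the transformed
#' `used_for_clustering` feature space (all clustered events, no subsample).
#' Each grid gets a deterministic seed derived from `som_params$seed` and
#' its position in the list; a failing grid is recorded with `failed = TRUE`
#' and the sweep continues.
#'
#' @param table a `cell_table` with `trans_expr`.
#' @param markers marker metadata data.frame.
#' @param grid_sizes data.frame with columns `xdim`, `ydim`.
#' @param som_params SOM training parameter overrides (see [train_som()]).
#' @return data.frame of class `sweep_result` with columns `xdim`, `ydim`,
#'   `n_clusters_total`, `n_clusters_nonempty`, `dbi`, `seed`, `failed`.
#' @export
grid_sweep <- function(table, markers, grid_sizes = default_grid_sizes(),
                       som_params = list()) {
  if (nrow(grid_sizes) == 0) stop("grid_sizes is empty", call. = FALSE)
  X <- clustering_matrix(table, markers)
  base_seed <- som_params$seed %||% 42L
  rows <- lapply(seq_len(nrow(grid_sizes)), function(g) {
    xd <- grid_sizes$xdim[g]; yd <- grid_sizes$ydim[g]
    seed_g <- base_seed + 1000L * g
    res <- tryCatch({
      model <- suppressWarnings(
        train_som(X, xd, yd,
                  utils::modifyList(som_params, list(seed = seed_g))))
      asg <- assign_bmu(model, X)
      occupied <- length(unique(asg$labels))
      dbi <- if (occupied >= 2) davies_bouldin_index(X, asg$labels) else NA_real_
      data.frame(xdim = xd, ydim = yd, n_clusters_total = xd * yd,
                 n_clusters_nonempty = occupied, dbi = dbi, seed = seed_g,
                 failed = FALSE)
    }, error = function(e) {
      warning(sprintf("grid %dx%d failed: %s", xd, yd, conditionMessage(e)),
              call. = FALSE)
      data.frame(xdim = xd, ydim = yd, n_clusters_total = xd * yd,
                 n_clusters_nonempty = NA_integer_, dbi = NA_real_,
                 seed = seed_g, failed = TRUE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Select a grid from a sweep result
#'
#' `"global_min"` returns the grid with the smallest DBI (ties broken by
#' fewest clusters, then lowest xdim). `"local_min"` walks the grids in
#' ascending total-cluster-count order and returns the first whose DBI is
#' lower than both neighbors; if the sequence has no interior local minimum
#' it falls back to the global minimum with a warning. `"manual"` echoes the
#' user's choice, which must be present in the sweep.
#'
#' @param sweep a `sweep_result`.
#' @param mode `"manual"`, `"global_min"` or `"local_min"`.
#' @param choice for manual mode, `c(xdim, ydim)`.
#' @return integer vector `c(xdim, ydim)`.
#' @export
select_grid <- function(sweep, mode = c("manual", "global_min", "local_min"),
                        choice = NULL) {
  mode <- match.arg(mode)
  ok <- sweep[!sweep$failed & !is.na(sweep$dbi), , drop = FALSE]
  if (nrow(ok) == 0) stop("sweep has no scored grids", call. = FALSE)

  if (mode == "manual") {
    if (is.null(choice) || length(choice) != 2) {
      stop("manual selection requires choice = c(xdim, ydim)", call. = FALSE)
    }
    hit <- sweep$xdim == choice[1] & sweep$ydim == choice[2]
    if (!any(hit)) stop(sprintf("grid %dx%d is not in the sweep",
                                choice[1], choice[2]), call. = FALSE)
    return(as.integer(choice))
  }

  ord <- ok[order(ok$n_clusters_total, ok$xdim), , drop = FALSE]
  if (mode == "local_min" && nrow(ord) >= 3) {
    d <- ord$dbi
    for (i in 2:(nrow(ord) - 1)) {
      if (d[i] < d[i - 1] && d[i] < d[i + 1]) {
        return(c(ord$xdim[i], ord$ydim[i]))
      }
    }
  }
  if (mode == "local_min") {
    warning("no interior local DBI minimum; falling back to the global minimum",
            call. = FALSE)
  }
  best <- ord[order(ord$dbi, ord$n_clusters_total, ord$xdim), , drop = FALSE][1, ]
  c(best$xdim, best$ydim)
}

#' Plot DBI against cluster count for a sweep
#'
#' The cluster-count-vs-DBI scatter used to choose a grid resolution.
#'
#' @param sweep a `sweep_result`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ok <- sweep[!sweep$failed & !is.na(sweep$dbi), , drop = FALSE]
  ok$grid <- paste0(ok$xdim, "x", ok$ydim)
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$n_clusters_total, y = .data$dbi)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$grid), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "Number of clusters (grid nodes)",
                  y = "Davies-Bouldin index",
                  title = "Cluster count vs DBI") +
    ggplot2::theme_bw()
}
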