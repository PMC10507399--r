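# Variance-stabilizing arcsinh transform, the cytometry standard.
# One global cofactor per run: ~5 for mass cytometry counts, larger
# (hundreds to thousands, e.g. 6000) for spectral flow intensities.

#' Arcsinh-transform raw expression values
#'
#' Computes `asinh(raw / cofactor)` elementwise. The transform is defined on
#' all of R, so negative values (possible after compensation/unmixing) pass
#' through untruncated.
#'
#' @param raw numeric matrix (or vector) of raw intensities.
#' @param cofactor positive scaling cofactor (default 5).
#' @return transformed matrix of the same shape.
#' @export
arcsinh_transform <- function(raw, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    stop("arcsinh cofactor must be a single positive number", call. = FALSE)
  }
  asinh(raw / cofactor)
}

#' Attach the transformed matrix to a cell table
#'
#' Applies [arcsinh_transform()] to `raw_expr` and stores the result as
#' `trans_expr`. Tables loaded from an already-transformed matrix (no
#' `raw_expr`) are returned unchanged.
#'
#' @param table a `cell_table`.
#' @param cofactor positive arcsinh cofactor.
#' @return the table with `trans_expr` populated.
#' @export
transform_cells <- function(table, cofactor = 5) {
  if (is.null(table$raw_expr)) {
    if (is.null(table$trans_expr)) {
      stop("cell table has neither raw nor transformed expression",
           call. = FALSE)
    }
    return(table)
  }
  table$trans_expr <- arcsinh_transform(table$raw_expr, cofactor)
  table
}

# Feature-set helpers: each downstream stage sees only the markers its
# usage flag selects, always on the transformed (unscaled) values.
marker_matrix <- function(table, markers, flag) {
  use <- markers[[flag]]
  if (!any(use)) {
    stop("no markers flagged ", flag, " in the marker metadata", call. = FALSE)
  }
  if (is.null(table$trans_expr)) {
    stop("cell table has no transformed expression; run transform_cells()",
         call. = FALSE)
  }
  table$trans_expr[, markers$channel_name[use], drop = FALSE]
}

#' Clustering feature matrix
#'
#' The transformed, unscaled expression restricted to markers flagged
#' `used_for_clustering`. This is the only input clustering ever sees
#' (never the embedding coordinates).
#'
#' @param table a `cell_table` with `trans_expr`.
#' @param markers marker metadata data.frame.
#' @return event x marker numeric matrix.
#' @export
clustering_matrix <- function(table, markers) {
  marker_matrix(table, markers, "used_for_clustering")
}
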