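# The central event container: expression matrices row-aligned with
# per-cell metadata. Kept as a light S3 list (matrix-centric, like the
# cytometry packages this interoperates with) rather than a formal class.

#' Construct a cell table
#'
#' @param raw_expr event x channel matrix of raw intensities, or NULL when
#'   the input was already transformed.
#' @param trans_expr event x channel matrix on the arcsinh scale, or NULL
#'   before transformation.
#' @param cell_meta data.frame of per-event metadata (file_name, donor_id,
#'   pool_id, control_sample, and later cell_id, umap1/umap2, cluster).
#' @return object of class `cell_table`.
#' @export
cell_table <- function(raw_expr = NULL, trans_expr = NULL, cell_meta) {
  n <- nrow(cell_meta)
  for (m in list(raw_expr, trans_expr)) {
    if (!is.null(m) && nrow(m) != n) {
      stop("expression matrix and cell_meta are not row-aligned", call. = FALSE)
    }
  }
  structure(list(raw_expr = raw_expr, trans_expr = trans_expr,
                 cell_meta = cell_meta),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  ch <- colnames(x$trans_expr %||% x$raw_expr)
  cat(sprintf("cell_table: %d events x %d channels\n",
              nrow(x$cell_meta), length(ch)))
  cat("  raw_expr:  ", if (is.null(x$raw_expr)) "absent" else "present", "\n")
  cat("  trans_expr:", if (is.null(x$trans_expr)) "absent" else "present", "\n")
  cat("  meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of events in a cell table
#' @param table a `cell_table`.
#' @return integer event count.
#' @export
n_events <- function(table) nrow(table$cell_meta)

subset_cells <- function(table, idx) {
  cell_table(
    raw_expr = if (!is.null(table$raw_expr)) table$raw_expr[idx, , drop = FALSE],
    trans_expr = if (!is.null(table$trans_expr)) table$trans_expr[idx, , drop = FALSE],
    cell_meta = table$cell_meta[idx, , drop = FALSE]
  )
}

#' Load a directory of FCS files into a cell table
#'
#' Reads every file listed in the file metadata (in metadata row order),
#' restricts and orders channels per the marker metadata, concatenates the
#' events and copies per-file metadata onto each event.
#'
#' @param fcs_dir directory containing the FCS files.
#' @param files data.frame from [read_file_metadata()].
#' @param markers data.frame from [read_marker_metadata()].
#' @return a `cell_table` with `raw_expr` populated.
#' @export
load_fcs_directory <- function(fcs_dir, files, markers) {
  paths <- file.path(fcs_dir, files$file_name)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("FCS file(s) not found in ", fcs_dir, ": ",
         paste(files$file_name[missing], collapse = ", "), call. = FALSE)
  }
  chunks <- vector("list", nrow(files))
  metas <- vector("list", nrow(files))
  for (i in seq_len(nrow(files))) {
    fcs <- read_fcs(paths[i])
    absent <- setdiff(markers$channel_name, colnames(fcs$data))
    if (length(absent)) {
      stop(sprintf("channel not found: '%s' missing from file %s",
                   absent[1], files$file_name[i]), call. = FALSE)
    }
    mat <- fcs$data[, markers$channel_name, drop = FALSE]
    if (nrow(mat) == 0) {
      warning("empty FCS file contributes zero events: ", files$file_name[i],
              call. = FALSE)
    }
    chunks[[i]] <- mat
    metas[[i]] <- data.frame(
      file_name = rep(files$file_name[i], nrow(mat)),
      donor_id = rep(files$donor_id[i], nrow(mat)),
      pool_id = rep(files$pool_id[i], nrow(mat)),
      control_sample = rep(files$control_sample[i], nrow(mat)),
      stringsAsFactors = FALSE
    )
  }
  raw <- do.call(rbind, chunks)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  assign_cell_ids(cell_table(raw_expr = raw, cell_meta = meta))
}

#' Load a pre-computed expression matrix into a cell table
#'
#' Entry point for batch-corrected matrices (cells in rows, markers in
#' columns) or imaging-derived intensity tables that were already arcsinh
#' transformed upstream.
#'
#' @param matrix_path CSV of the expression matrix; columns must cover all
#'   `marker_name` entries of `markers` (extra columns are dropped with a
#'   warning).
#' @param cell_meta_path CSV of per-cell metadata, row-aligned with the
#'   matrix; NULL assigns a single synthetic file entry.
#' @param markers marker metadata data.frame.
#' @param already_transformed when TRUE the values are stored as `trans_expr`
#'   and no arcsinh transform is applied later; otherwise they are raw.
#' @return a `cell_table`.
#' @export
load_matrix <- function(matrix_path, cell_meta_path = NULL, markers,
                        already_transformed = FALSE) {
  mat_df <- read.csv(matrix_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(mat_df) == 0) stop("empty input: ", matrix_path, call. = FALSE)
  need <- markers$marker_name
  absent <- setdiff(need, names(mat_df))
  if (length(absent)) {
    stop("matrix is missing marker column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(mat_df), need)
  if (length(extra)) {
    warning("matrix: ignoring extra column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(mat_df[, need, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(mat_df[, need, drop = FALSE], is.numeric, TRUE))
    stop("matrix: non-numeric values in column '", need[bad[1]], "'",
         call. = FALSE)
  }
  colnames(mat) <- markers$channel_name

  if (!is.null(cell_meta_path)) {
    meta <- read.csv(cell_meta_path, stringsAsFactors = FALSE)
    if (nrow(meta) != nrow(mat)) {
      stop(sprintf("alignment error: matrix has %d rows but cell metadata %d",
                   nrow(mat), nrow(meta)), call. = FALSE)
    }
  } else {
    meta <- data.frame(file_name = rep("matrix_input", nrow(mat)),
                       donor_id = "matrix_input", pool_id = "pool1",
                       control_sample = FALSE, stringsAsFactors = FALSE)
  }
  tab <- if (already_transformed) {
    cell_table(trans_expr = mat, cell_meta = meta)
  } else {
    cell_table(raw_expr = mat, cell_meta = meta)
  }
  if (is.null(tab$cell_meta$cell_id)) tab <- assign_cell_ids(tab) else tab
}

#' Attach unique per-cell barcodes
#'
#' Barcodes follow the `<sample_id>_<cell_index>` convention, where the
#' sample id is the FCS file name without extension and the cell index is
#' 1-based within each source file.
#'
#' @param table a `cell_table` whose metadata carries `file_name`.
#' @return the table with a `cell_id` metadata column.
#' @export
assign_cell_ids <- function(table) {
  meta <- table$cell_meta
  stem <- tools::file_path_sans_ext(meta$file_name)
  runs <- rle(meta$file_name)  # index within each contiguous file block
  idx <- sequence(runs$lengths)
  ids <- paste0(stem, "_", idx)
  if (anyDuplicated(ids)) {
    stop("duplicate cell_id generated; is a file listed twice in the metadata?",
         call. = FALSE)
  }
  table$cell_meta$cell_id <- ids
  table
}

#' Drop control-sample events
#'
#' Removes every event whose `control_sample` flag is TRUE, preserving the
#' order of the remaining events.
#'
#' @param table a `cell_table`.
#' @return the filtered table.
#' @export
remove_controls <- function(table) {
  keep <- !table$cell_meta$control_sample
  if (!any(keep)) warning("all events were controls; table is now empty",
                          call. = FALSE)
  subset_cells(table, which(keep))
}

#' Subsample events per source file
#'
#' Draws up to `n_per_file` events uniformly without replacement from each
#' source file; files with fewer events keep everything. Reproducible for a
#' fixed seed.
#'
#' @param table a `cell_table`.
#' @param n_per_file maximum events retained per file (>= 1).
#' @param seed integer RNG seed.
#' @return the subsampled table (original event order preserved).
#' @export
subsample_per_file <- function(table, n_per_file, seed = 42L) {
  stopifnot(n_per_file >= 1)
  files <- unique(table$cell_meta$file_name)
  keep <- with_seed(seed, {
    unlist(lapply(files, function(f) {
      idx <- which(table$cell_meta$file_name == f)
      if (length(idx) <= n_per_file) idx
      else sort(sample(idx, n_per_file))
    }))
  })
  subset_cells(table, sort(keep))
}
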