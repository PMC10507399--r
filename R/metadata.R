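# Run metadata intake: file_metadata.csv, marker_metadata.csv, config.yml.

FILE_MD_COLS <- c("file_name", "donor_id", "pool_id", "control_sample")
MARKER_MD_COLS <- c("channel_name", "marker_name", "used_for_UMAP",
                    "used_for_clustering", "used_for_scaffold")

read_csv_tolerant <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, required, label)
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s: ignoring extra column(s): %s", label,
                    paste(extra, collapse = ", ")), call. = FALSE)
    df <- df[, required, drop = FALSE]
  }
  df
}

#' Read the per-file sample metadata table
#'
#' Expects columns `file_name`, `donor_id`, `pool_id` (batch) and
#' `control_sample` (boolean). Boolean values may be written as
#' true/false, TRUE/FALSE or 1/0.
#'
#' @param path path to `file_metadata.csv`.
#' @return data.frame with one row per FCS file.
#' @export
read_file_metadata <- function(path) {
  df <- read_csv_tolerant(path, FILE_MD_COLS, "file_metadata")
  if (anyDuplicated(df$file_name)) {
    stop("file_metadata: duplicated file_name value(s): ",
         paste(unique(df$file_name[duplicated(df$file_name)]), collapse = ", "),
         call. = FALSE)
  }
  df$control_sample <- parse_boolean(df$control_sample, "control_sample",
                                     "file_metadata")
  df
}

#' Read the per-channel marker metadata table
#'
#' Expects columns `channel_name`, `marker_name` and the three boolean usage
#' flags `used_for_UMAP`, `used_for_clustering`, `used_for_scaffold`, which
#' independently steer the embedding, clustering and landmark feature sets.
#'
#' @param path path to `marker_metadata.csv`.
#' @return data.frame with one row per channel.
#' @export
read_marker_metadata <- function(path) {
  df <- read_csv_tolerant(path, MARKER_MD_COLS, "marker_metadata")
  if (anyDuplicated(df$channel_name)) {
    stop("marker_metadata: duplicated channel_name value(s)", call. = FALSE)
  }
  for (col in c("used_for_UMAP", "used_for_clustering", "used_for_scaffold")) {
    df[[col]] <- parse_boolean(df[[col]], col, "marker_metadata")
  }
  if (!any(df$used_for_clustering)) {
    stop("marker_metadata: at least one marker must be used_for_clustering",
         call. = FALSE)
  }
  df
}

#' Default run configuration
#'
#' Returns the full configuration list with every key at its default:
#' arcsinh cofactor 5; UMAP n_neighbors 15, min_dist 0.1, spread 0.1,
#' learning_rate 0.5, random initialization; SOM backend with a 6 x 6 grid,
#' metaclustering off, k = 3 metaclusters when on; CLARA k = 20, euclidean
#' metric, 50 subsamples.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    fcs_dir = NULL,
    output_dir = NULL,
    file_metadata_path = NULL,
    marker_metadata_path = NULL,
    arcsinh_cofactor = 5,
    umap = list(n_neighbors = 15L, min_dist = 0.1, spread = 0.1,
                learning_rate = 0.5, init = "random", seed = 42L),
    backend = "som",
    som = list(xdim = 6L, ydim = 6L, meta_clustering = FALSE, k = 3L,
               seed = 42L),
    clara = list(k = 20L, metric = "euclidean", samples = 50L, seed = 42L),
    grid_sizes_path = NULL,
    subsample_per_file = NULL,
    remove_controls = FALSE,
    landmark_dir = NULL,
    truth_labels_path = NULL
  )
}

validate_config <- function(cfg) {
  if (!cfg$backend %in% c("som", "clara")) {
    stop("config: unknown backend '", cfg$backend,
         "' (expected 'som' or 'clara')", call. = FALSE)
  }
  if (!is.numeric(cfg$arcsinh_cofactor) || cfg$arcsinh_cofactor <= 0) {
    stop("config: arcsinh_cofactor must be > 0", call. = FALSE)
  }
  if (cfg$som$xdim < 1 || cfg$som$ydim < 1) {
    stop("config: som xdim and ydim must be >= 1", call. = FALSE)
  }
  if (!is.null(cfg$subsample_per_file) && cfg$subsample_per_file < 1) {
    stop("config: subsample_per_file must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Absent keys are filled with the defaults of [default_config()]; nested
#' `umap`, `som` and `clara` blocks are merged key-wise.
#'
#' @param path path to `config.yml`.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (key in names(user)) {
    if (key %in% c("umap", "som", "clara") && is.list(user[[key]])) {
      for (sub in names(user[[key]])) cfg[[key]][[sub]] <- user[[key]][[sub]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Read all three run metadata files
#'
#' Convenience wrapper reading file metadata, marker metadata and the YAML
#' configuration in one call.
#'
#' @param file_md_path path to `file_metadata.csv`.
#' @param marker_md_path path to `marker_metadata.csv`.
#' @param config_path path to `config.yml`.
#' @return list with elements `files`, `markers`, `config`.
#' @export
read_metadata <- function(file_md_path, marker_md_path, config_path) {
  list(files = read_file_metadata(file_md_path),
       markers = read_marker_metadata(marker_md_path),
       config = read_config(config_path))
}
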