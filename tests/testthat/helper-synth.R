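# Shared fixtures, all generated in code.

# A small fast design for IO / pipeline tests.
small_design <- function(events = 300, files = 3, seed = 101,
                         controls = integer(0)) {
  synth_design(events_per_file = events, n_files = files,
               control_files = controls, seed = seed)
}

# A transformed cell table plus markers, ready for clustering tests.
small_clustered_input <- function(events = 400, seed = 202) {
  ds <- generate_dataset(small_design(events = events, seed = seed))
  tab <- transform_cells(ds$table, 5)
  list(table = tab, markers = ds$markers,
       X = clustering_matrix(tab, ds$markers),
       truth = ds$table$cell_meta$truth_label)
}

# Random small labelled instances for metric cross-checks.
random_partition_pair <- function(n, k1, k2, seed) {
  withr_seed <- seed
  set.seed(withr_seed)
  list(truth = sample(letters[seq_len(k1)], n, replace = TRUE),
       pred = sample(LETTERS[seq_len(k2)], n, replace = TRUE))
}

# Minimal marker metadata for hand-built tables.
toy_markers <- function(channels, umap = TRUE, clustering = TRUE,
                        scaffold = TRUE) {
  data.frame(channel_name = channels, marker_name = channels,
             used_for_UMAP = umap, used_for_clustering = clustering,
             used_for_scaffold = scaffold, stringsAsFactors = FALSE)
}

# Hand-built cell table from a matrix.
toy_table <- function(X, file = "f1.fcs", transform = TRUE) {
  meta <- data.frame(file_name = file, donor_id = "d1", pool_id = "p1",
                     control_sample = FALSE, stringsAsFactors = FALSE)
  meta <- meta[rep(1, nrow(X)), , drop = FALSE]
  rownames(meta) <- NULL
  tab <- assign_cell_ids(cell_table(raw_expr = X, cell_meta = meta))
  if (transform) tab <- transform_cells(tab, 5)
  tab
}
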