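write_min_config <- function(lines = character()) {
  p <- tempfile(fileext = ".yml")
  writeLines(c("output_dir: /tmp/x", lines), p)
  p
}

test_that("config defaults are filled for absent keys", {
  cfg <- read_config(write_min_config())
  expect_equal(cfg$arcsinh_cofactor, 5)
  expect_equal(cfg$umap$n_neighbors, 15L)
  expect_equal(cfg$umap$min_dist, 0.1)
  expect_equal(cfg$umap$spread, 0.1)
  expect_equal(cfg$umap$learning_rate, 0.5)
  expect_equal(cfg$umap$init, "random")
  expect_equal(cfg$som$xdim, 6L)
  expect_equal(cfg$som$ydim, 6L)
  expect_false(cfg$som$meta_clustering)
  expect_equal(cfg$som$k, 3L)
  expect_equal(cfg$clara$k, 20L)
  expect_equal(cfg$clara$metric, "euclidean")
  expect_equal(cfg$clara$samples, 50L)
})

test_that("non-default grids and backends are validated", {
  cfg <- read_config(write_min_config(c("som:", "  xdim: 2", "  ydim: 4")))
  expect_equal(cfg$som$xdim * cfg$som$ydim, 8)
  expect_error(read_config(write_min_config("backend: phenograph")),
               "unknown backend")
  expect_error(read_config(write_min_config("arcsinh_cofactor: 0")),
               "cofactor")
  expect_error(read_config(write_min_config(c("som:", "  xdim: 0"))),
               "xdim")
})

test_that("metadata schema errors name the offending column or row", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(channel_name = "a", marker_name = "a",
                       used_for_UMAP = TRUE, used_for_scaffold = TRUE),
            p, row.names = FALSE)
  expect_error(read_marker_metadata(p), "used_for_clustering")

  write.csv(data.frame(file_name = c("a.fcs", "b.fcs"), donor_id = "d",
                       pool_id = "p", control_sample = c("true", "maybe")),
            p, row.names = FALSE)
  expect_error(read_file_metadata(p), "row 2")

  write.csv(data.frame(file_name = c("a.fcs", "a.fcs"), donor_id = "d",
                       pool_id = "p", control_sample = "false"),
            p, row.names = FALSE)
  expect_error(read_file_metadata(p), "duplicated file_name")
})

test_that("boolean vocabulary covers true/false, TRUE/FALSE and 1/0", {
  expect_equal(cytosweep:::parse_boolean(
    c("true", "FALSE", "1", "0", "TRUE", "false"), "f"),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("extra metadata columns are ignored with a warning", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(file_name = "a.fcs", donor_id = "d", pool_id = "p",
                       control_sample = "0", surprise = 1),
            p, row.names = FALSE)
  expect_warning(md <- read_file_metadata(p), "surprise")
  expect_false("surprise" %in% names(md))
})

test_that("barcodes follow <sample_id>_<index> with 1-based per-file index", {
  ds <- generate_dataset(small_design(events = 3, files = 2))
  ids <- ds$table$cell_meta$cell_id
  expect_equal(ids, c("sample01_1", "sample01_2", "sample01_3",
                      "sample02_1", "sample02_2", "sample02_3"))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("a file appearing twice yields a duplicate-barcode error", {
  meta <- data.frame(file_name = c("a.fcs", "a.fcs", "b.fcs", "a.fcs"),
                     donor_id = "d", pool_id = "p", control_sample = FALSE)
  X <- matrix(1, 4, 2, dimnames = list(NULL, c("c1", "c2")))
  expect_error(assign_cell_ids(cell_table(raw_expr = X, cell_meta = meta)),
               "duplicate cell_id")
})

test_that("control removal filters flagged events and keeps order", {
  ds <- generate_dataset(small_design(events = 50, files = 4,
                                      controls = c(1, 3)))
  out <- remove_controls(ds$table)
  expect_equal(n_events(out), 100)
  expect_true(all(!out$cell_meta$control_sample))
  expect_equal(out$cell_meta$cell_id,
               ds$table$cell_meta$cell_id[!ds$table$cell_meta$control_sample])

  none <- generate_dataset(small_design(events = 10, files = 2))
  expect_equal(remove_controls(none$table)$cell_meta, none$table$cell_meta)

  all_ctrl <- generate_dataset(small_design(events = 10, files = 2,
                                            controls = 1:2))
  expect_warning(empty <- remove_controls(all_ctrl$table), "empty")
  expect_equal(n_events(empty), 0)
})

test_that("per-file subsampling caps at availability and totals correctly", {
  ds <- generate_dataset(small_design(events = 200, files = 5))
  expect_equal(n_events(subsample_per_file(ds$table, 1000, seed = 1)), 1000)
  sub <- subsample_per_file(ds$table, 40, seed = 1)
  expect_equal(n_events(sub), 200)
  expect_equal(unname(table(sub$cell_meta$file_name)), rep(40L, 5),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(sub$cell_meta$cell_id) > 0)
})

test_that("subsampling is seed-reproducible and seeds differ as expected", {
  ds <- generate_dataset(small_design(events = 2000, files = 1))
  a <- subsample_per_file(ds$table, 500, seed = 7)
  b <- subsample_per_file(ds$table, 500, seed = 7)
  expect_identical(a$cell_meta$cell_id, b$cell_meta$cell_id)

  # overlap of two independent draws of 500 from 2000 is hypergeometric:
  # mean 125, sd = sqrt(500 * (500/2000) * (1500/2000) * (1500/1999)) ~ 8.4
  c2 <- subsample_per_file(ds$table, 500, seed = 8)
  ov <- length(intersect(a$cell_meta$cell_id, c2$cell_meta$cell_id))
  expect_lt(abs(ov - 125), 3 * 8.4)
})

test_that("matrix intake honors already_transformed and validates shape", {
  ds <- generate_dataset(small_design(events = 30, files = 1))
  tab <- transform_cells(ds$table, 5)
  mp <- tempfile(fileext = ".csv")
  df <- as.data.frame(tab$trans_expr)
  names(df) <- ds$markers$marker_name
  write.csv(df, mp, row.names = FALSE)

  got <- load_matrix(mp, NULL, ds$markers, already_transformed = TRUE)
  expect_null(got$raw_expr)
  expect_equal(unname(got$trans_expr), unname(tab$trans_expr),
               tolerance = 1e-8)
  # transform_cells is a no-op on pre-transformed input
  expect_equal(transform_cells(got, 5)$trans_expr, got$trans_expr)

  df$extra_col <- 1
  write.csv(df, mp, row.names = FALSE)
  expect_warning(load_matrix(mp, NULL, ds$markers, TRUE), "extra_col")

  write.csv(df[0, ], mp, row.names = FALSE)
  expect_error(load_matrix(mp, NULL, ds$markers, TRUE), "empty input")

  write.csv(as.data.frame(tab$trans_expr)[, 1:3], mp, row.names = FALSE)
  expect_error(load_matrix(mp, NULL, ds$markers, TRUE), "missing marker")
})

test_that("cell ids stay unique through control removal and subsampling", {
  ds <- generate_dataset(small_design(events = 100, files = 4,
                                      controls = 2))
  out <- subsample_per_file(remove_controls(ds$table), 30, seed = 3)
  expect_false(anyDuplicated(out$cell_meta$cell_id) > 0)
  expect_equal(n_events(out), 90)
})
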