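test_that("population draws match the design proportions", {
  d <- synth_design(events_per_file = 10000, n_files = 1, seed = 1401)
  ds <- generate_dataset(d)
  counts <- table(ds$table$cell_meta$truth_label)
  p <- default_populations()$proportions[names(counts)]
  sds <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) < 3 * sds))
})

test_that("generation is bitwise seed-deterministic", {
  d <- synth_design(events_per_file = 200, n_files = 2, seed = 1402)
  a <- generate_dataset(d)
  b <- generate_dataset(d)
  expect_identical(a$table$raw_expr, b$table$raw_expr)
  expect_identical(a$table$cell_meta, b$table$cell_meta)
  d2 <- synth_design(events_per_file = 200, n_files = 2, seed = 1403)
  expect_false(identical(generate_dataset(d2)$table$raw_expr,
                         a$table$raw_expr))
})

test_that("raw values are non-negative and transform back to the signatures", {
  d <- synth_design(events_per_file = 5000, n_files = 1, seed = 1404)
  ds <- generate_dataset(d)
  expect_true(all(ds$table$raw_expr >= 0))
  tab <- transform_cells(ds$table, d$cofactor)
  sig <- default_populations()$signatures
  for (p in rownames(sig)) {
    rows <- tab$cell_meta$truth_label == p
    got <- colMeans(tab$trans_expr[rows, ])
    # high markers sit near their signature mean (truncation only affects
    # the low tail near zero)
    hi <- sig[p, ] >= 2
    expect_equal(unname(got[hi]), unname(sig[p, hi]), tolerance = 0.05)
  }
})

test_that("zero batch shift leaves batch-wise population means equal", {
  d <- synth_design(events_per_file = 4000, n_files = 2, n_batches = 2,
                    batch_shifts = c(0, 0), seed = 1405)
  ds <- generate_dataset(d)
  tab <- transform_cells(ds$table, d$cofactor)
  rows1 <- tab$cell_meta$pool_id == "batch1" &
    tab$cell_meta$truth_label == "T_CD4"
  rows2 <- tab$cell_meta$pool_id == "batch2" &
    tab$cell_meta$truth_label == "T_CD4"
  m1 <- colMeans(tab$trans_expr[rows1, ]); m2 <- colMeans(tab$trans_expr[rows2, ])
  se <- 0.3 * sqrt(1 / sum(rows1) + 1 / sum(rows2))
  expect_true(all(abs(m1 - m2) < 4 * se))

  # and a non-zero shift moves them
  d3 <- synth_design(events_per_file = 4000, n_files = 2, n_batches = 2,
                     batch_shifts = c(0, 0.5), seed = 1405)
  tab3 <- transform_cells(generate_dataset(d3)$table, d3$cofactor)
  r1 <- tab3$cell_meta$pool_id == "batch1"
  r2 <- tab3$cell_meta$pool_id == "batch2"
  expect_gt(mean(tab3$trans_expr[r2, ]) - mean(tab3$trans_expr[r1, ]), 0.4)
})

test_that("invalid designs are rejected", {
  pops <- default_populations()
  pops$proportions <- pops$proportions * 2
  expect_error(synth_design(populations = pops), "sum to 1")
  pops2 <- default_populations()
  pops2$spreads[1, 1] <- 0
  expect_error(synth_design(populations = pops2), "positive")
})

test_that("the written dataset is a complete, loadable run input", {
  d <- synth_design(events_per_file = 60, n_files = 2, seed = 1406)
  ds <- generate_dataset(d)
  dir <- tempfile()
  paths <- write_dataset(ds, dir, d)
  expect_true(all(file.exists(unlist(paths[c("file_metadata",
                                             "marker_metadata", "config",
                                             "truth_labels")]))))
  md <- read_metadata(paths$file_metadata, paths$marker_metadata,
                      paths$config)
  tab <- load_fcs_directory(paths$fcs_dir, md$files, md$markers)
  expect_equal(n_events(tab), 120)
  expect_identical(tab$cell_meta$cell_id, ds$table$cell_meta$cell_id)
  rel <- abs(tab$raw_expr - ds$table$raw_expr) /
    pmax(abs(ds$table$raw_expr), 1e-6)
  expect_lt(max(rel), 1e-5)
  expect_equal(length(list.files(paths$landmark_dir, pattern = "\\.fcs$")),
               5)
})

test_that("imaging tables keep coordinates inside the declared rectangle", {
  d <- synth_design(events_per_file = 500, n_files = 1, seed = 1407)
  img <- generate_imaging_table(d, width = 400, height = 250)
  expect_true(all(img$regions$x >= 0 & img$regions$x <= 400))
  expect_true(all(img$regions$y >= 0 & img$regions$y <= 250))
  expect_setequal(unique(img$regions$region), c("stroma", "tumor"))
  expect_equal(nrow(img$expr), 500)
  # region boundary honored
  expect_true(all(img$regions$x[img$regions$region == "stroma"] < 200))
})
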