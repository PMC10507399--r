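region_fixture <- function(labels, regions, C = max(labels)) {
  list(asg = cytosweep:::new_cluster_assignment(labels, C, "som"),
       reg = data.frame(cell_id = paste0("r", seq_along(labels)),
                        x = seq_along(labels), y = 0, region = regions,
                        stringsAsFactors = FALSE))
}

test_that("region frequencies are per-region probability vectors", {
  fx <- region_fixture(c(1, 1, 2, 2, 1, 2), rep(c("stroma", "tumor"), 3))
  fr <- region_frequencies(fx$asg, fx$reg)
  expect_equal(unname(colSums(fr)), c(1, 1), tolerance = 1e-12)

  solo <- region_fixture(rep(1, 6), rep(c("stroma", "tumor"), 3), C = 1)
  fr1 <- region_frequencies(solo$asg, solo$reg)
  expect_equal(unname(fr1["cluster_1", ]), c(1, 1))

  bal <- region_fixture(rep(c(1, 2), 10), rep(c("stroma", "tumor"), each = 10))
  expect_equal(unname(as.vector(region_frequencies(bal$asg, bal$reg))),
               rep(0.5, 4))
})

test_that("empty regions are dropped with a warning", {
  fx <- region_fixture(c(1, 2, 1, 2), rep("stroma", 4))
  fx$reg$region <- factor(fx$reg$region, levels = c("stroma", "tumor"))
  expect_warning(fr <- region_frequencies(fx$asg, fx$reg), "tumor")
  expect_equal(colnames(fr), "stroma")
})

test_that("log2 enrichment matches hand values and flags undefined clusters", {
  freq <- matrix(c(0.2, 0.2, 0.2, 0.05, 0.6, 0), 3, 2, byrow = TRUE,
                 dimnames = list(paste0("cluster_", 1:3),
                                 c("stroma", "tumor")))
  en <- log2_enrichment(freq)
  expect_equal(en$log2fc[1], 0)      # equal frequencies
  expect_equal(en$log2fc[2], 2)      # 0.2 / 0.05 = 4
  expect_true(is.na(en$log2fc[3]))   # tumor frequency 0 -> undefined
  expect_false(en$defined[3])
  expect_error(log2_enrichment(freq[, 1, drop = FALSE]), "absent")
})

test_that("enrichment is antisymmetric under region swap", {
  set.seed(1200)
  freq <- matrix(runif(8, 0.01, 1), 4, 2,
                 dimnames = list(NULL, c("stroma", "tumor")))
  freq <- sweep(freq, 2, colSums(freq), "/")
  a <- log2_enrichment(freq)
  b <- log2_enrichment(freq[, c(2, 1)], stroma = "tumor", tumor = "stroma")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
})

test_that("overlay export carries coordinates and honors cluster filters", {
  fx <- region_fixture(c(1, 2, 1, 2, 3), rep("stroma", 5))
  p <- tempfile(fileext = ".csv")
  all_rows <- export_overlay(fx$asg, fx$reg, p)
  expect_equal(nrow(all_rows), 5)
  expect_equal(names(read.csv(p)), c("cell_id", "x", "y", "cluster"))

  only2 <- export_overlay(fx$asg, fx$reg, p, cluster_filter = 2)
  expect_equal(only2$cluster, c(2, 2))

  none <- export_overlay(fx$asg, fx$reg, p, cluster_filter = integer(0))
  expect_equal(nrow(none), 0)
  expect_equal(names(read.csv(p)), c("cell_id", "x", "y", "cluster"))
})

test_that("a planted stroma-confined population shows positive enrichment", {
  d <- synth_design(events_per_file = 4000, n_files = 1, seed = 1301)
  img <- generate_imaging_table(d, stroma_bias = c(
    T_CD4 = 0.95, T_CD8 = 0.5, B = 0.5, Monocyte = 0.5, NK = 0.5))
  pops <- sort(unique(img$truth))
  asg <- cytosweep:::new_cluster_assignment(match(img$truth, pops),
                                            length(pops), "som")
  en <- log2_enrichment(region_frequencies(asg, img$regions))
  cd4 <- which(pops == "T_CD4")
  expect_true(en$defined[cd4])
  expect_gt(en$log2fc[cd4], 0)
  expect_gt(en$log2fc[cd4], max(abs(en$log2fc[-cd4])))
})

test_that("spatially uniform populations show near-zero enrichment", {
  d <- synth_design(events_per_file = 6000, n_files = 1, seed = 1302)
  img <- generate_imaging_table(d)  # uniform placement
  pops <- sort(unique(img$truth))
  asg <- cytosweep:::new_cluster_assignment(match(img$truth, pops),
                                            length(pops), "som")
  en <- log2_enrichment(region_frequencies(asg, img$regions))
  # permutation spread of log2fc under uniform placement
  perm <- replicate(200, {
    shuf <- img$regions
    shuf$region <- sample(shuf$region)
    max(abs(log2_enrichment(region_frequencies(asg, shuf))$log2fc))
  })
  expect_lt(max(abs(en$log2fc)), mean(perm) + 3 * sd(perm))
  expect_true(all(img$regions$x >= 0 & img$regions$x <= 1000))
  expect_true(all(img$regions$y >= 0 & img$regions$y <= 1000))
})
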