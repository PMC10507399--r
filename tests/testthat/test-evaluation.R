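label_df <- function(ids, labels) data.frame(cell_id = ids, label = labels,
                                             stringsAsFactors = FALSE)

test_that("accuracy is the exact-match fraction over shared barcodes", {
  t4 <- label_df(paste0("c", 1:4), c("A", "A", "B", "B"))
  expect_equal(accuracy(t4, t4), 1)
  expect_equal(accuracy(t4, label_df(paste0("c", 1:4),
                                     c("A", "A", "B", "C"))), 0.75)
  expect_equal(accuracy(t4, label_df(paste0("c", 1:4),
                                     c("x", "y", "z", "w"))), 0)
  expect_error(accuracy(t4, label_df(paste0("d", 1:4), "A")),
               "no shared barcodes")
  # only the intersection of barcodes is scored
  expect_equal(accuracy(t4, label_df(c("c1", "c9"), c("A", "Q"))), 1)
})

test_that("ARI matches hand-enumerated instances", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "a", "b", "b"),
                                   c("x", "y", "x", "y")), -0.5)
  # all-one-cluster prediction collapses to 0
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), rep(1, 5)), 0)
  expect_error(adjusted_rand_index(1, 1), "at least 2")
})

test_that("Fowlkes-Mallows matches pair enumeration by hand", {
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(fowlkes_mallows(c("a", "a", "b", "b"),
                               c("x", "y", "x", "y")), 0)
  expect_equal(fowlkes_mallows(c("a", "a", "a"), c("x", "x", "y")),
               1 / sqrt(3), tolerance = 1e-12)
  expect_error(fowlkes_mallows(1:3, 1:3), "no same-cluster pairs")
})

test_that("mutual information matches closed forms and entropy bounds", {
  expect_equal(mutual_information(c(1, 1, 2, 2), rep(1, 4)), 0)
  expect_equal(mutual_information(c(1, 1, 2, 2), c(2, 2, 9, 9)), log(2),
               tolerance = 1e-12)
  expect_equal(mutual_information(c(1, 1, 2, 2), c(2, 2, 9, 9),
                                  unit = "bits"), 1, tolerance = 1e-12)
  for (s in 1:20) {
    pp <- random_partition_pair(60, 3, 4, 800 + s)
    mi <- mutual_information(pp$truth, pp$pred)
    expect_lte(mi, min(entropy_nat(pp$truth), entropy_nat(pp$pred)) + 1e-12)
    expect_gte(mi, 0)
  }
})

test_that("ARI, FM and MI agree with brute-force enumeration", {
  worst <- c(ari = 0, fm = 0, mi = 0)
  for (s in 1:100) {
    n <- sample(10:60, 1)
    pp <- random_partition_pair(n, sample(2:5, 1), sample(2:5, 1), 900 + s)
    worst["ari"] <- max(worst["ari"],
                        abs(adjusted_rand_index(pp$truth, pp$pred) -
                              ari_brute(pp$truth, pp$pred)))
    worst["fm"] <- max(worst["fm"],
                       abs(fowlkes_mallows(pp$truth, pp$pred) -
                             fm_brute(pp$truth, pp$pred)))
    worst["mi"] <- max(worst["mi"],
                       abs(mutual_information(pp$truth, pp$pred) -
                             mi_brute(pp$truth, pp$pred)))
  }
  expect_lt(max(worst), 1e-9)
})

test_that("metrics other than accuracy are invariant to label renaming", {
  pp <- random_partition_pair(80, 4, 4, 1001)
  renamed <- paste0("new_", pp$pred)
  expect_equal(adjusted_rand_index(pp$truth, renamed),
               adjusted_rand_index(pp$truth, pp$pred))
  expect_equal(fowlkes_mallows(pp$truth, renamed),
               fowlkes_mallows(pp$truth, pp$pred))
  expect_equal(mutual_information(pp$truth, renamed),
               mutual_information(pp$truth, pp$pred))
})

test_that("the concordance protocol is deterministic and complete", {
  set.seed(1100)
  ids <- paste0("c", 1:3000)
  truth <- label_df(ids, sample(c("A", "B", "C"), 3000, replace = TRUE))
  r1 <- suppressWarnings(concordance_report(truth, truth,
                                            n_per_repeat = 1000,
                                            n_repeats = 10, seed = 5))
  r2 <- suppressWarnings(concordance_report(truth, truth,
                                            n_per_repeat = 1000,
                                            n_repeats = 10, seed = 5))
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 10)
  expect_equal(unname(r1$means[c("accuracy", "adjusted_rand_index",
                                 "fowlkes_mallows")]),
               c(1, 1, 1))
  expect_gt(r1$means[["mutual_information"]], 0)
})

test_that("planted label confusion lands at the expected accuracy", {
  set.seed(1101)
  n <- 20000
  ids <- paste0("c", seq_len(n))
  lab <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
  flip <- sample(n, n / 10)
  pred_lab <- lab
  pred_lab[flip] <- vapply(lab[flip], function(l) {
    sample(setdiff(c("A", "B", "C", "D"), l), 1)
  }, "")
  rep <- concordance_report(label_df(ids, lab), label_df(ids, pred_lab),
                            n_per_repeat = 10000, n_repeats = 10, seed = 2)
  sd_bin <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(rep$means[["accuracy"]] - 0.9), 3 * sd_bin)
})

test_that("the tetramer gate thresholds at mean + 3 sd", {
  v <- c(rep(0, 99), 1000)
  # mean 10, sd ~99.99 -> threshold ~310 < 1000: only the outlier passes
  expect_equal(which(tetramer_gate(v)), 100)

  expect_warning(gt <- tetramer_gate(rep(5, 50)), "zero variance")
  expect_false(any(gt))

  set.seed(1102)
  x <- rnorm(10000)
  frac <- mean(tetramer_gate(x, ddof = 1))
  p <- pnorm(3, lower.tail = FALSE)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
})
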