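# Concordance between cluster-derived per-cell annotations and
# ground-truth (manually gated) labels: accuracy, adjusted Rand index,
# Fowlkes-Mallows index and mutual information, computed on repeated
# random subsamples of shared barcodes. Plus the tetramer-positivity gate.

join_labels <- function(truth, pred) {
  for (df in list(truth, pred)) {
    require_columns(df, c("cell_id", "label"), "label table")
  }
  shared <- intersect(truth$cell_id, pred$cell_id)
  if (length(shared) == 0) {
    stop("no shared barcodes between truth and prediction", call. = FALSE)
  }
  data.frame(cell_id = shared,
             truth = truth$label[match(shared, truth$cell_id)],
             pred = pred$label[match(shared, pred$cell_id)],
             stringsAsFactors = FALSE)
}

#' Annotation accuracy
#'
#' Fraction of shared barcodes whose truth and predicted label strings match
#' exactly. Both sides must use the same annotation vocabulary (cluster
#' labels are expert-assigned cell-type strings); no label matching is
#' applied.
#'
#' @param truth,pred data.frames with columns `cell_id`, `label`.
#' @return scalar in `[0, 1]`.
#' @export
accuracy <- function(truth, pred) {
  j <- join_labels(truth, pred)
  mean(j$truth == j$pred)
}

pair_counts <- function(n_ij) {
  # helper on a contingency table: same-cluster pair counts
  choose2 <- function(x) x * (x - 1) / 2
  list(sum_ij = sum(choose2(n_ij)),
       sum_a = sum(choose2(rowSums(n_ij))),
       sum_b = sum(choose2(colSums(n_ij))),
       total = choose2(sum(n_ij)))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same cells, via the Hubert-Arabie contingency-table formula.
#'
#' @param truth,pred vectors of cluster labels over the same cells.
#' @return scalar (1 for identical partitions, ~0 at chance).
#' @export
adjusted_rand_index <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) < 2) stop("ARI needs at least 2 cells", call. = FALSE)
  pc <- pair_counts(table(truth, pred))
  expected <- pc$sum_a * pc$sum_b / pc$total
  denom <- (pc$sum_a + pc$sum_b) / 2 - expected
  if (denom == 0) return(0)  # both partitions trivial
  (pc$sum_ij - expected) / denom
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall over same-cluster pairs:
#' `TP / sqrt((TP + FP) * (TP + FN))`.
#'
#' @param truth,pred vectors of cluster labels over the same cells.
#' @return scalar in `[0, 1]`.
#' @export
fowlkes_mallows <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) < 2) stop("FM needs at least 2 cells", call. = FALSE)
  pc <- pair_counts(table(truth, pred))
  if (pc$sum_a == 0 || pc$sum_b == 0) {
    stop("Fowlkes-Mallows undefined: a partition has no same-cluster pairs",
         call. = FALSE)
  }
  pc$sum_ij / sqrt(pc$sum_a * pc$sum_b)
}

#' Mutual information between two partitions
#'
#' `MI = sum_ij p_ij * log(p_ij / (p_i * p_j))`, reported in nats by
#' default (`unit = "bits"` divides by log 2).
#'
#' @param truth,pred vectors of cluster labels over the same cells.
#' @param unit `"nats"` (default) or `"bits"`.
#' @return non-negative scalar.
#' @export
mutual_information <- function(truth, pred, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  stopifnot(length(truth) == length(pred))
  p_ij <- table(truth, pred) / length(truth)
  p_i <- rowSums(p_ij); p_j <- colSums(p_ij)
  terms <- p_ij * log(p_ij / outer(p_i, p_j))
  mi <- sum(terms[p_ij > 0])
  mi <- max(mi, 0)  # guard tiny negative rounding
  if (unit == "bits") mi / log(2) else mi
}

#' Repeated-subsample concordance report
#'
#' Per repeat, samples `n_per_repeat` shared barcodes without replacement
#' (seed derived from the master seed), computes accuracy, adjusted Rand
#' index, Fowlkes-Mallows index and mutual information, then reports
#' per-repeat values and their means.
#'
#' @param truth,pred data.frames with columns `cell_id`, `label`.
#' @param n_per_repeat cells sampled per repeat (default 10000; capped at
#'   the overlap size with a warning).
#' @param n_repeats number of repeats (default 10).
#' @param seed master seed; repeat r uses `seed + r`.
#' @return list of class `concordance_report` with `per_repeat`
#'   (data.frame), `means` (named numeric), `n_per_repeat`, `n_repeats`,
#'   `seeds`.
#' @export
concordance_report <- function(truth, pred, n_per_repeat = 10000L,
                               n_repeats = 10L, seed = 42L) {
  j <- join_labels(truth, pred)
  if (nrow(j) < n_per_repeat) {
    warning(sprintf("only %d shared barcodes; capping n_per_repeat", nrow(j)),
            call. = FALSE)
    n_per_repeat <- nrow(j)
  }
  seeds <- seed + seq_len(n_repeats)
  rows <- lapply(seq_len(n_repeats), function(r) {
    idx <- with_seed(seeds[r], sample.int(nrow(j), n_per_repeat))
    s <- j[idx, ]
    data.frame(repeat_id = r, seed = seeds[r],
               accuracy = mean(s$truth == s$pred),
               adjusted_rand_index = adjusted_rand_index(s$truth, s$pred),
               fowlkes_mallows = fowlkes_mallows(s$truth, s$pred),
               mutual_information = mutual_information(s$truth, s$pred))
  })
  per_repeat <- do.call(rbind, rows)
  means <- colMeans(per_repeat[, c("accuracy", "adjusted_rand_index",
                                   "fowlkes_mallows", "mutual_information")])
  structure(list(per_repeat = per_repeat, means = means,
                 n_per_repeat = n_per_repeat, n_repeats = n_repeats,
                 seeds = seeds),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %d repeats x %d cells\n",
              x$n_repeats, x$n_per_repeat))
  print(round(x$means, 4))
  invisible(x)
}

#' Gate tetramer-positive events
#'
#' An event is positive when its raw intensity is at least 3 standard
#' deviations above the mean intensity of all provided events.
#'
#' @param intensities numeric vector of raw channel intensities (>= 2
#'   events).
#' @param n_sd positivity threshold in standard deviations (default 3).
#' @param ddof degrees-of-freedom correction for the sd: 1 (default, sample
#'   sd) or 0 (population sd).
#' @return logical vector, TRUE for positive events.
#' @export
tetramer_gate <- function(intensities, n_sd = 3, ddof = 1) {
  if (length(intensities) < 2) stop("tetramer gate needs >= 2 events",
                                    call. = FALSE)
  mu <- mean(intensities)
  s <- sd(intensities)
  if (ddof == 0) s <- s * sqrt((length(intensities) - 1) / length(intensities))
  if (s == 0) {
    warning("zero variance: no events can exceed the gate", call. = FALSE)
    return(rep(FALSE, length(intensities)))
  }
  intensities >= mu + n_sd * s
}
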