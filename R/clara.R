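# CLARA (Clustering LARge Applications): PAM k-medoids run on seeded
# subsamples, keeping the medoid set that minimizes the mean dissimilarity
# of ALL events to their nearest medoid.

cross_dist <- function(X, M, metric = "euclidean") {
  if (metric == "euclidean") {
    # direct per-medoid differences: exact zeros for identical points
    # (the quadratic-expansion shortcut loses ~1e-8 to cancellation)
    out <- matrix(0, nrow(X), nrow(M))
    for (j in seq_len(nrow(M))) {
      out[, j] <- sqrt(rowSums(sweep(X, 2, M[j, ])^2))
    }
    out
  } else if (metric == "manhattan") {
    out <- matrix(0, nrow(X), nrow(M))
    for (j in seq_len(nrow(M))) {
      out[, j] <- rowSums(abs(sweep(X, 2, M[j, ])))
    }
    out
  } else {
    stop("unsupported metric '", metric, "'", call. = FALSE)
  }
}

#' PAM k-medoids on a dissimilarity matrix
#'
#' Classical partitioning around medoids: a greedy BUILD phase followed by
#' steepest-descent SWAP until no single medoid/non-medoid exchange lowers
#' the total dissimilarity. The cost after BUILD and after each accepted
#' swap is recorded in the `costs` attribute of the result (the trajectory
#' is non-increasing by construction).
#'
#' @param D symmetric n x n dissimilarity matrix.
#' @param k number of medoids (1 <= k <= n).
#' @return integer vector of medoid indices with attributes `costs`
#'   (cost trajectory) and `labels` (nearest-medoid assignment, ties to the
#'   lowest medoid position).
#' @export
pam_fit <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n) stop("pam: k must be in 1..n", call. = FALSE)

  # BUILD: start from the most central point, then greedily add the
  # candidate that most reduces the total nearest-medoid dissimilarity.
  medoids <- which.min(rowSums(D))
  dnear <- D[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(h) sum(pmax(dnear - D[, h], 0)), 0)
    best <- cand[which.max(gain)]
    medoids <- c(medoids, best)
    dnear <- pmin(dnear, D[, best])
  }
  cost <- sum(dnear)
  costs <- cost

  # SWAP: steepest descent over all (medoid, non-medoid) exchanges.
  repeat {
    dm <- D[, medoids, drop = FALSE]
    if (length(medoids) > 1) {
      ord <- apply(dm, 1, order)  # k x n
      best_id <- ord[1, ]
      dbest <- dm[cbind(seq_len(n), best_id)]
      dsecond <- dm[cbind(seq_len(n), ord[2, ])]
    } else {
      best_id <- rep(1L, n)
      dbest <- dm[, 1]
      dsecond <- rep(Inf, n)
    }

    best_delta <- 0
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      base <- ifelse(best_id == mi, dsecond, dbest)
      for (h in nonmed) {
        newcost <- sum(pmin(base, D[, h]))
        delta <- newcost - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cost <- cost + best_delta
    costs <- c(costs, cost)
  }

  dm <- D[, medoids, drop = FALSE]
  labels <- max.col(-dm, ties.method = "first")
  structure(medoids, costs = costs, labels = labels)
}

#' Cluster events with CLARA
#'
#' Draws `samples` seeded subsamples of size `min(n, 40 + 2k)`, fits PAM
#' (BUILD + SWAP) to each, scores every fitted medoid set by the mean
#' dissimilarity of all events to their nearest medoid, and returns the
#' assignment of the best-scoring set.
#'
#' @param X event x marker numeric matrix.
#' @param k number of clusters (default 20).
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @param samples number of subsamples (default 50).
#' @param seed integer RNG seed.
#' @return a `cluster_assignment` with `C = k`; elements `medoids` (row
#'   indices into `X`) and `cost` (mean nearest-medoid dissimilarity) are
#'   attached, and attribute `swap_costs` holds the PAM cost trajectory of
#'   the winning subsample.
#' @export
clara_cluster <- function(X, k = 20, metric = "euclidean", samples = 50,
                          seed = 42L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k <= 0) stop("clara: k must be positive", call. = FALSE)
  if (k > n) stop(sprintf("clara: k (%d) exceeds event count (%d)", k, n),
                  call. = FALSE)
  stopifnot(samples >= 1)
  sampsize <- min(n, 40 + 2 * k)

  idx_sets <- with_seed(seed, {
    lapply(seq_len(samples), function(s) sort(sample.int(n, sampsize)))
  })
  best <- NULL
  for (idx in idx_sets) {
    D <- as.matrix(dist(X[idx, , drop = FALSE], method = metric))
    fit <- pam_fit(D, k)
    med_global <- idx[as.integer(fit)]
    dall <- cross_dist(X, X[med_global, , drop = FALSE], metric)
    score <- mean(dall[cbind(seq_len(n), max.col(-dall, ties.method = "first"))])
    if (is.null(best) || score < best$score - 1e-12) {
      best <- list(score = score, medoids = med_global, dall = dall,
                   costs = attr(fit, "costs"))
    }
  }
  labels <- max.col(-best$dall, ties.method = "first")
  out <- new_cluster_assignment(labels, k, "clara")
  out$medoids <- best$medoids
  out$cost <- best$score
  attr(out, "swap_costs") <- best$costs
  out
}
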