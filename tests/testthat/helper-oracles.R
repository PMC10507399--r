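# Independent brute-force reference implementations used to cross-check
# the package's vectorized metric code. These deliberately take different
# computational routes (explicit loops, pair enumeration, entropy
# identities) from the implementations they validate.

# Davies-Bouldin by direct loops over the definition.
dbi_brute <- function(X, labels) {
  ids <- sort(unique(labels))
  K <- length(ids)
  cent <- list(); S <- numeric(K)
  for (i in seq_len(K)) {
    rows <- which(labels == ids[i])
    cent[[i]] <- apply(X[rows, , drop = FALSE], 2, mean)
    dists <- numeric(length(rows))
    for (r in seq_along(rows)) {
      dists[r] <- sqrt(sum((X[rows[r], ] - cent[[i]])^2))
    }
    S[i] <- mean(dists)
  }
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / K
}

# Pairwise counts by explicit enumeration over all unordered pairs.
pair_enum <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) tp <- tp + 1
      else if (!st && sp) fp <- fp + 1
      else if (st && !sp) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

ari_brute <- function(truth, pred) {
  pc <- pair_enum(truth, pred)
  n <- length(truth)
  total <- n * (n - 1) / 2
  sum_ij <- pc["tp"]
  sum_a <- pc["tp"] + pc["fn"]
  sum_b <- pc["tp"] + pc["fp"]
  expected <- sum_a * sum_b / total
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(0)
  unname((sum_ij - expected) / denom)
}

fm_brute <- function(truth, pred) {
  pc <- pair_enum(truth, pred)
  unname(pc["tp"] / sqrt((pc["tp"] + pc["fp"]) * (pc["tp"] + pc["fn"])))
}

# Mutual information via the entropy identity H(T) + H(P) - H(T,P).
entropy_nat <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

mi_brute <- function(truth, pred) {
  joint <- paste(truth, pred, sep = "\r")
  entropy_nat(truth) + entropy_nat(pred) - entropy_nat(joint)
}
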