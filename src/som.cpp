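#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing map training.
//
// X          n x p data matrix (events in rows)
// codes      m x p initial codebook (modified copy returned)
// order      0-based row indices of X, one per training step (length = rlen * n,
//            generated in R so that presentation order is governed by R's RNG)
// alpha_*    learning rate, decayed linearly over the steps
// radius_*   bubble neighborhood radius on the grid, decayed linearly
// grid_dist  m x m matrix of node-to-node grid distances
//
// A node is updated when its grid distance to the best-matching unit is
// <= the current radius (threshold/"bubble" neighborhood). BMU ties break
// toward the lowest node index (strict < comparison).
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, NumericMatrix codes,
                            IntegerVector order,
                            double alpha_start, double alpha_end,
                            double radius_start, double radius_end,
                            NumericMatrix grid_dist) {
  const int p = X.ncol();
  const int m = codes.nrow();
  const R_xlen_t T = order.size();
  NumericMatrix cb = clone(codes);

  for (R_xlen_t t = 0; t < T; ++t) {
    const int i = order[t];
    const double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double alpha = alpha_start - (alpha_start - alpha_end) * frac;
    const double radius = radius_start - (radius_start - radius_end) * frac;

    // best-matching unit
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d = 0.0;
      for (int c = 0; c < p; ++c) {
        const double diff = X(i, c) - cb(j, c);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = j; }
    }

    for (int j = 0; j < m; ++j) {
      if (grid_dist(bmu, j) <= radius) {
        for (int c = 0; c < p; ++c)
          cb(j, c) += alpha * (X(i, c) - cb(j, c));
      }
    }
  }
  return cb;
}

// Nearest-prototype assignment (1-based labels); ties go to the lowest index.
// [[Rcpp::export]]
IntegerVector map_to_codes_cpp(NumericMatrix X, NumericMatrix codes) {
  const int n = X.nrow(), p = X.ncol(), m = codes.nrow();
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d = 0.0;
      for (int c = 0; c < p; ++c) {
        const double diff = X(i, c) - codes(j, c);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = j; }
    }
    lab[i] = bmu + 1;
  }
  return lab;
}
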