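#include <Rcpp.h>
using namespace Rcpp;

// Neighborhood-preservation distance computed from the Gram matrix of the
// subset space: squared distances are d2(i,j) = sn[i] + sn[j] - 2 G(i,j).
// For each sample i the j-th nearest subset-space neighbour (ties to the
// smaller index, self excluded) is matched against the precomputed j-th
// reference-space neighbour, and the subset-space distance between the two
// neighbour points is accumulated.
//
// G:         N x N Gram matrix (tcrossprod of the subset coordinates)
// sn:        length-N squared row norms (diagonal of G)
// ref_order: N x k reference-space neighbour indices (1-based)
// [[Rcpp::export(name = ".np_from_gram")]]
double np_from_gram(NumericMatrix G, NumericVector sn, IntegerMatrix ref_order) {
  const int n = G.nrow();
  const int k = ref_order.ncol();
  std::vector<double> row(n);
  std::vector<int> sub_nb(k);
  const double* g = REAL(G);
  const double* s = REAL(sn);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* col = g + (size_t)i * n;   // symmetric: column i == row i
    const double si = s[i];
    for (int j = 0; j < n; ++j) row[j] = si + s[j] - 2.0 * col[j];
    row[i] = R_PosInf;
    for (int j = 0; j < k; ++j) {            // k arg-min sweeps
      int best = 0;
      double bv = R_PosInf;
      for (int l = 0; l < n; ++l) {
        if (row[l] < bv) { bv = row[l]; best = l; }
      }
      sub_nb[j] = best;
      row[best] = R_PosInf;
    }
    for (int j = 0; j < k; ++j) {
      int a = ref_order(i, j) - 1;
      int b = sub_nb[j];
      if (a == b) continue;
      double v = s[a] + s[b] - 2.0 * g[(size_t)b * n + a];
      acc += std::sqrt(v > 0.0 ? v : 0.0);
    }
  }
  return acc / (double)(n * k);
}
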