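#include <Rcpp.h>
using namespace Rcpp;

// Margin vectors z_i for the local-learning feature selector.
//
// Xt is the m x n *transposed* data matrix (features down the rows), so the
// per-sample feature vectors are contiguous in memory. For each sample i,
// the nearest-miss / nearest-hit probabilities over the opposite-class set
// M_i and same-class set H_i (r != i) are
//   P(r | w) prop-to exp(-d_w(i, r) / sigma),  d_w = sum_j w_j |x_ij - x_rj|,
// each distribution normalized to sum to 1 (softmax stabilized by shifting
// with the set's minimum distance). Then
//   z_i = E_miss |x_i - x_r| - E_hit |x_i - x_r|   (elementwise).
// Returns the n x m matrix of z_i rows. O(n^2 m).
// [[Rcpp::export]]
NumericMatrix margin_vectors_t_cpp(const NumericMatrix& Xt,
                                   const IntegerVector& y,
                                   const NumericVector& w,
                                   double sigma) {
  const int m = Xt.nrow(), n = Xt.ncol();
  if (y.size() != n) stop("length(y) != ncol(Xt)");
  if (w.size() != m) stop("length(w) != nrow(Xt)");
  NumericMatrix Z(n, m);
  std::vector<double> d(n), p(n), zi(m);
  const double* X = Xt.begin();
  const double* wp = w.begin();

  for (int i = 0; i < n; ++i) {
    const double* xi = X + (size_t)i * m;
    double dmin_miss = R_PosInf, dmin_hit = R_PosInf;
    for (int r = 0; r < n; ++r) {
      const double* xr = X + (size_t)r * m;
      double acc = 0.0;
      for (int j = 0; j < m; ++j)
        acc += wp[j] * std::fabs(xi[j] - xr[j]);
      d[r] = acc;
      if (y[r] != y[i]) {
        if (acc < dmin_miss) dmin_miss = acc;
      } else if (r != i) {
        if (acc < dmin_hit) dmin_hit = acc;
      }
    }
    if (!R_FINITE(dmin_miss)) stop("sample %d has no opposite-class neighbor", i + 1);
    if (!R_FINITE(dmin_hit)) stop("degenerate hit set: sample %d is alone in its class", i + 1);

    double sum_miss = 0.0, sum_hit = 0.0;
    for (int r = 0; r < n; ++r) {
      if (y[r] != y[i]) {
        p[r] = std::exp(-(d[r] - dmin_miss) / sigma);
        sum_miss += p[r];
      } else if (r != i) {
        p[r] = std::exp(-(d[r] - dmin_hit) / sigma);
        sum_hit += p[r];
      } else {
        p[r] = 0.0;
      }
    }
    std::fill(zi.begin(), zi.end(), 0.0);
    for (int r = 0; r < n; ++r) {
      if (p[r] == 0.0) continue;
      const double* xr = X + (size_t)r * m;
      double coef = (y[r] != y[i]) ? p[r] / sum_miss : -p[r] / sum_hit;
      for (int j = 0; j < m; ++j)
        zi[j] += coef * std::fabs(xi[j] - xr[j]);
    }
    for (int j = 0; j < m; ++j) Z(i, j) = zi[j];
  }
  return Z;
}
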