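#include <Rcpp.h>
using namespace Rcpp;

// Fuzzy tolerance R(x, y) of a test vector y against every pooled object
// (rows of X): min over attributes of 1 - |x_a - y_a| / (a_max - a_min).
// Test values are clamped into [a_min, a_max] first; zero-range attributes
// contribute similarity 1.
// [[Rcpp::export(name = ".tolerance_scan")]]
NumericVector tolerance_scan(NumericMatrix X, NumericVector y,
                             NumericVector a_min, NumericVector a_max) {
  int n = X.nrow(), d = X.ncol();
  if (y.size() != d) stop("feature length mismatch");
  NumericVector out(n);
  std::vector<double> yc(d), range(d);
  for (int j = 0; j < d; ++j) {
    double lo = a_min[j], hi = a_max[j];
    double v = y[j];
    if (v < lo) v = lo;
    if (v > hi) v = hi;
    yc[j] = v;
    range[j] = hi - lo;
  }
  for (int i = 0; i < n; ++i) {
    double m = 1.0;
    for (int j = 0; j < d; ++j) {
      if (range[j] <= 0.0) continue; // constant attribute: similarity 1
      double s = 1.0 - std::fabs(X(i, j) - yc[j]) / range[j];
      if (s < m) m = s;
    }
    out[i] = m;
  }
  return out;
}

// Euclidean distance from y to every row of X (KNN baseline).
// [[Rcpp::export(name = ".euclidean_scan")]]
NumericVector euclidean_scan(NumericMatrix X, NumericVector y) {
  int n = X.nrow(), d = X.ncol();
  if (y.size() != d) stop("feature length mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < d; ++j) {
      double diff = X(i, j) - y[j];
      acc += diff * diff;
    }
    out[i] = std::sqrt(acc);
  }
  return out;
}
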