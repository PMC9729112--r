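#include <Rcpp.h>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information, algorithm 1:
//   I(X;Y) = psi(k) + psi(N) - < psi(n_x + 1) + psi(n_y + 1) >
// where n_x (n_y) counts points strictly within the distance to the k-th
// joint-space neighbour, all distances in the max (Chebyshev) norm.
// Brute-force O(N^2) neighbour search; N here is a few thousand at most.

static double maxnorm(const NumericMatrix& a, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < a.ncol(); ++c) {
    double v = std::fabs(a(i, c) - a(j, c));
    if (v > d) d = v;
  }
  return d;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (n <= k + 1) stop("need more samples than k + 1");

  double acc = 0.0;
  std::vector<double> kd(k);
  for (int i = 0; i < n; ++i) {
    // k smallest joint distances to i (excluding i): simple insertion list
    int filled = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = maxnorm(x, i, j);
      double dy = maxnorm(y, i, j);
      double dz = dx > dy ? dx : dy;
      if (filled < k) {
        kd[filled++] = dz;
        if (filled == k) std::make_heap(kd.begin(), kd.end());
      } else if (dz < kd.front()) {
        std::pop_heap(kd.begin(), kd.end());
        kd[k - 1] = dz;
        std::push_heap(kd.begin(), kd.end());
      }
    }
    const double eps = kd.front();
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (maxnorm(x, i, j) < eps) ++nx;
      if (maxnorm(y, i, j) < eps) ++ny;
    }
    acc += R::digamma(nx + 1) + R::digamma(ny + 1);
  }
  return R::digamma(k) + R::digamma(n) - acc / n;
}
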