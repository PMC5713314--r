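#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// First Kraskov-Stoegbauer-Grassberger mutual information estimator
// (max-norm neighbourhoods):
//   mi = digamma(k) + digamma(n) - <digamma(n_x + 1) + digamma(n_y + 1)>
// where n_x(i) counts points with |x_j - x_i| < eps_i and eps_i is the
// max-norm distance to the k-th nearest neighbour of point i.
static double ksg_pair(const double* x, const double* y, int n, int k) {
  std::vector<double> dz(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = std::abs(x[j] - x[i]);
      double dy = std::abs(y[j] - y[i]);
      dz[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(dz.begin(), dz.begin() + (k - 1), dz.begin() + m);
    double eps = dz[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::abs(x[j] - x[i]) < eps) ++nx;
      if (std::abs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi;
}

// [[Rcpp::export(name = ".ksg_mi_pair")]]
double ksg_mi_pair(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (n < 2 * k + 2) stop("need at least 2k + 2 observations");
  return ksg_pair(x.begin(), y.begin(), n, k);
}

// [[Rcpp::export(name = ".ksg_mi_matrix")]]
NumericMatrix ksg_mi_matrix(NumericMatrix X, int k) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2 * k + 2) stop("need at least 2k + 2 observations");
  NumericMatrix M(p, p);
  for (int a = 0; a < p; ++a) {
    for (int b = a + 1; b < p; ++b) {
      double mi = ksg_pair(&X(0, a), &X(0, b), n, k);
      if (mi < 0.0) mi = 0.0;
      M(a, b) = mi;
      M(b, a) = mi;
    }
    Rcpp::checkUserInterrupt();
  }
  return M;
}
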