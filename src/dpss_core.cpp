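#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Count of eigenvalues of the symmetric tridiagonal matrix (diag d, offdiag e)
// strictly below x (Sturm sequence / LDL^T inertia count).
static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e, double x) {
  const int n = (int) d.size();
  int cnt = 0;
  double q = d[0] - x;
  if (q < 0) ++cnt;
  for (int i = 1; i < n; ++i) {
    double denom = (q == 0.0) ? 1e-300 : q;
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q < 0) ++cnt;
  }
  return cnt;
}

// Solve (T - lambda I) v = b for tridiagonal T by Gaussian elimination with
// partial pivoting (fill-in limited to a second superdiagonal).
static void tridiag_shifted_solve(const std::vector<double>& d,
                                  const std::vector<double>& e,
                                  double lambda, std::vector<double>& v) {
  const int n = (int) d.size();
  std::vector<double> a(n, 0.0), bb(n, 0.0), c(n, 0.0), c2(n, 0.0);
  for (int i = 0; i < n; ++i) bb[i] = d[i] - lambda;
  for (int i = 0; i + 1 < n; ++i) { a[i + 1] = e[i]; c[i] = e[i]; }
  for (int i = 0; i + 1 < n; ++i) {
    if (std::fabs(a[i + 1]) > std::fabs(bb[i])) {   // pivot rows i, i+1
      std::swap(bb[i], a[i + 1]);
      std::swap(c[i], bb[i + 1]);
      std::swap(c2[i], c[i + 1]);
      std::swap(v[i], v[i + 1]);
    }
    if (bb[i] == 0.0) bb[i] = 1e-300;
    double m = a[i + 1] / bb[i];
    bb[i + 1] -= m * c[i];
    c[i + 1] -= m * c2[i];
    v[i + 1] -= m * v[i];
  }
  if (bb[n - 1] == 0.0) bb[n - 1] = 1e-300;
  v[n - 1] /= bb[n - 1];
  if (n > 1) v[n - 2] = (v[n - 2] - c[n - 2] * v[n - 1]) / bb[n - 2];
  for (int i = n - 3; i >= 0; --i)
    v[i] = (v[i] - c[i] * v[i + 1] - c2[i] * v[i + 2]) / bb[i];
}

// Discrete prolate spheroidal sequences via the classical symmetric
// tridiagonal formulation: d_i = ((n-1-2i)/2)^2 cos(2*pi*W), e_i = i(n-i)/2.
// The K tapers with the largest eigenvalues are found by Sturm bisection and
// inverse iteration; each is normalised to unit energy.
// [[Rcpp::export(name = ".dpss_core")]]
NumericMatrix dpss_core(int n, double nw, int K) {
  if (n < 2 || K < 1 || K > n) stop("invalid dpss order");
  const double W = nw / n;                 // normalised half-bandwidth
  const double c2w = std::cos(2.0 * M_PI * W);
  std::vector<double> d(n), e(n - 1);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1 - 2.0 * i) / 2.0;
    d[i] = h * h * c2w;
  }
  for (int i = 1; i < n; ++i) e[i - 1] = i * (n - i) / 2.0;

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = (i > 0 ? std::fabs(e[i - 1]) : 0.0) +
               (i < n - 1 ? std::fabs(e[i]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  const double span = hi - lo;

  NumericMatrix out(n, K);
  std::vector<double> v(n);
  for (int j = 1; j <= K; ++j) {          // j-th largest eigenvalue
    double a = lo, b = hi;
    for (int it = 0; it < 120 && (b - a) > 1e-14 * span; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) >= n - j + 1) b = mid; else a = mid;
    }
    double lambda = 0.5 * (a + b);

    // inverse iteration from a deterministic start vector
    for (int i = 0; i < n; ++i)
      v[i] = std::sin((i + 1.0) * j * M_PI / (n + 1.0)) + 1e-4 * ((i * 7 + j) % 13 - 6);
    for (int it = 0; it < 4; ++it) {
      tridiag_shifted_solve(d, e, lambda + span * 1e-15, v);
      // orthogonalise against previously found tapers (safety for close eigs)
      for (int p = 0; p < j - 1; ++p) {
        double dot = 0;
        for (int i = 0; i < n; ++i) dot += v[i] * out(i, p);
        for (int i = 0; i < n; ++i) v[i] -= dot * out(i, p);
      }
      double nrm = 0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // sign convention: positive mean for symmetric tapers, else positive
    // initial lobe
    double s = 0;
    for (int i = 0; i < n; ++i) s += v[i];
    if (std::fabs(s) < 1e-8) {
      s = 0;
      for (int i = 0; i < n / 2; ++i) s += v[i];
    }
    if (s < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    for (int i = 0; i < n; ++i) out(i, j - 1) = v[i];
  }
  return out;
}
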