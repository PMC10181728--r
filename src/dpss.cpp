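#include <Rcpp.h>
#include <cmath>
#include <vector>

// Discrete prolate spheroidal (Slepian) sequences via the symmetric
// tridiagonal formulation: the DPSS of length n and half-bandwidth
// W = nw/n are the eigenvectors belonging to the k largest eigenvalues of
// the matrix with
//   diag[i]    = ((n-1-2i)/2)^2 * cos(2*pi*W),   i = 0..n-1
//   offdiag[i] = (i+1)*(n-1-i)/2,                i = 0..n-2
// Eigenvalues are located by Sturm-count bisection and eigenvectors by
// shifted inverse iteration with a pivoted tridiagonal solve, O(n) per
// eigenpair, so full-measurement taper sets (n ~ 1e5) stay cheap.

// Number of eigenvalues of (d, e) strictly less than x (LDL^T sign count).
static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e, double x) {
  const int n = (int)d.size();
  const double tiny = 1e-300;
  int cnt = 0;
  double q = d[0] - x;
  if (q < 0.0) ++cnt;
  for (int i = 1; i < n; ++i) {
    double qp = q;
    if (std::fabs(qp) < tiny) qp = (qp < 0.0) ? -tiny : tiny;
    q = d[i] - x - e[i - 1] * e[i - 1] / qp;
    if (q < 0.0) ++cnt;
  }
  return cnt;
}

// Solve (T - lambda I) y = b with partial pivoting (Golub & Van Loan style
// for tridiagonal systems); d, e as above. Overwrites b with the solution.
static void tridiag_solve_shifted(const std::vector<double>& d,
                                  const std::vector<double>& e,
                                  double lambda, std::vector<double>& b) {
  const int n = (int)d.size();
  std::vector<double> a(n), c0(n, 0.0), c1(n, 0.0), c2(n, 0.0);
  for (int i = 0; i < n; ++i) a[i] = d[i] - lambda;
  // Rows: [sub, diag, sup] -> eliminate with row swaps where needed.
  std::vector<double> diag(n), sup1(n, 0.0), sup2(n, 0.0);
  std::vector<double> sub(n, 0.0);
  for (int i = 0; i < n; ++i) {
    diag[i] = a[i];
    if (i < n - 1) sup1[i] = e[i];
    if (i > 0) sub[i] = e[i - 1];
  }
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(sub[i + 1]) > std::fabs(diag[i])) {
      std::swap(diag[i], sub[i + 1]);
      std::swap(sup1[i], diag[i + 1]);
      std::swap(sup2[i], sup1[i + 1]);
      std::swap(b[i], b[i + 1]);
    }
    double piv = diag[i];
    if (std::fabs(piv) < 1e-300) piv = (piv < 0.0) ? -1e-300 : 1e-300;
    double m = sub[i + 1] / piv;
    diag[i + 1] -= m * sup1[i];
    sup1[i + 1] -= m * sup2[i];
    b[i + 1] -= m * b[i];
  }
  // Back substitution.
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    if (i + 1 < n) s -= sup1[i] * b[i + 1];
    if (i + 2 < n) s -= sup2[i] * b[i + 2];
    double piv = diag[i];
    if (std::fabs(piv) < 1e-300) piv = (piv < 0.0) ? -1e-300 : 1e-300;
    b[i] = s / piv;
  }
}

// [[Rcpp::export(name = ".dpss_tapers")]]
Rcpp::NumericMatrix dpss_tapers(int n, double nw, int k) {
  if (n < 2) Rcpp::stop("taper length must be at least 2");
  if (k < 1 || k > n) Rcpp::stop("taper count out of range");
  if (nw <= 0 || nw >= n / 2.0) Rcpp::stop("time-bandwidth product out of range");

  const double W = nw / n;
  const double c = std::cos(2.0 * M_PI * W);
  std::vector<double> d(n), e(n - 1);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1.0 - 2.0 * i) / 2.0;
    d[i] = h * h * c;
  }
  for (int i = 0; i < n - 1; ++i) e[i] = (i + 1.0) * (n - 1.0 - i) / 2.0;

  // Gershgorin interval.
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(e[i - 1]);
    if (i < n - 1) r += std::fabs(e[i]);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  const double span = hi - lo;
  const double tol = span * 1e-14;

  Rcpp::NumericMatrix out(n, k);
  std::vector<std::vector<double> > found;

  for (int j = 0; j < k; ++j) {
    // Locate the (n-1-j)-th eigenvalue (0-based, ascending): bisect until
    // the count of eigenvalues below the midpoint brackets index n-1-j.
    int target = n - 1 - j;  // want count(<=x) to cross target+1
    double a = lo, b = hi;
    for (int it = 0; it < 200 && (b - a) > tol; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) > target) b = mid; else a = mid;
    }
    double lambda = 0.5 * (a + b);

    // Inverse iteration from a deterministic start vector.
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i)
      v[i] = std::sin((j + 1.0) * M_PI * (i + 1.0) / (n + 1.0)) + 1e-8 * ((i % 7) - 3);
    double shift = lambda + span * 1e-13;  // keep the solve nonsingular
    for (int it = 0; it < 4; ++it) {
      tridiag_solve_shifted(d, e, shift, v);
      // Orthogonalize against previously found eigenvectors.
      for (size_t p = 0; p < found.size(); ++p) {
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += v[i] * found[p][i];
        for (int i = 0; i < n; ++i) v[i] -= dot * found[p][i];
      }
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      if (nrm < 1e-300) Rcpp::stop("inverse iteration collapsed");
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }

    // Polarity convention: symmetric (even-order) tapers have positive mean;
    // antisymmetric ones start with a positive lobe.
    double s = 0.0;
    if (j % 2 == 0) {
      for (int i = 0; i < n; ++i) s += v[i];
    } else {
      for (int i = 0; i < n / 2; ++i) s += v[i];
    }
    if (s < 0.0) for (int i = 0; i < n; ++i) v[i] = -v[i];

    for (int i = 0; i < n; ++i) out(i, j) = v[i];
    found.push_back(v);
  }
  return out;
}
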