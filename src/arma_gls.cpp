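#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ARMA(1,1) autocorrelations rho(0..n-1).
// rho(1) = (1 + phi*theta)(phi + theta) / (1 + 2*phi*theta + theta^2),
// rho(k) = phi * rho(k-1) for k >= 2.
static void arma11_rho(double phi, double theta, int n, std::vector<double>& r) {
  r.assign(n, 0.0);
  r[0] = 1.0;
  if (n > 1) {
    double denom = 1.0 + 2.0 * phi * theta + theta * theta;
    r[1] = (1.0 + phi * theta) * (phi + theta) / denom;
    for (int k = 2; k < n; ++k) r[k] = phi * r[k - 1];
  }
}

// [[Rcpp::export]]
NumericVector arma11_acf_cpp(double phi, double theta, int max_lag) {
  std::vector<double> r;
  arma11_rho(phi, theta, max_lag + 1, r);
  NumericVector out(max_lag + 1);
  for (int k = 0; k <= max_lag; ++k) out[k] = r[k];
  return out;
}

// Whiten the columns of Z against the ARMA(1,1) correlation matrix R of its
// row order: returns W with W = D^{-1/2} L^{-1} Z where R = L D L' (unit
// lower-triangular L from the Levinson-Durbin recursion), plus log|R|.
// Then W'W = Z' R^{-1} Z exactly.
// [[Rcpp::export]]
List arma11_whiten_cpp(double phi, double theta, NumericMatrix Z) {
  int n = Z.nrow(), c = Z.ncol();
  std::vector<double> r;
  arma11_rho(phi, theta, n, r);
  NumericMatrix W(n, c);
  std::vector<double> a(n, 0.0), a_prev(n, 0.0);
  double v = 1.0, logdet = 0.0;
  for (int j = 0; j < c; ++j) W(0, j) = Z(0, j);
  for (int m = 1; m < n; ++m) {
    // reflection coefficient for order m
    double acc = r[m];
    for (int j = 1; j < m; ++j) acc -= a[j - 1] * r[m - j];
    double k = acc / v;
    for (int j = 0; j < m; ++j) a_prev[j] = a[j];
    for (int j = 1; j < m; ++j) a[j - 1] = a_prev[j - 1] - k * a_prev[m - j - 1];
    a[m - 1] = k;
    v *= (1.0 - k * k);
    if (!(v > 1e-300)) stop("ARMA(1,1) correlation matrix numerically singular");
    logdet += std::log(v);
    double sv = std::sqrt(v);
    for (int col = 0; col < c; ++col) {
      double pred = 0.0;
      for (int j = 1; j <= m; ++j) pred += a[j - 1] * Z(m - j, col);
      W(m, col) = (Z(m, col) - pred) / sv;
    }
  }
  return List::create(_["W"] = W, _["logdet"] = logdet);
}

// Profile Gaussian log-likelihood of a linear model with ARMA(1,1)
// correlated errors, beta and sigma2 profiled out:
//   betahat = (X'R^-1 X)^-1 X'R^-1 y,  sigma2hat = RSS_w / n,
//   ll = -n/2 log(2 pi sigma2hat) - 1/2 log|R| - n/2.
// Returns -Inf on singular normal equations. Fast path for the optimizer.
// [[Rcpp::export]]
double arma11_profile_loglik_cpp(double phi, double theta,
                                 NumericMatrix X, NumericVector y) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> r;
  arma11_rho(phi, theta, n, r);
  // raw copies: the Rcpp accessors are too slow for the inner loops
  std::vector<double> x0(static_cast<size_t>(n) * p), y0(n);
  const double* xsrc = X.begin();
  std::copy(xsrc, xsrc + static_cast<size_t>(n) * p, x0.begin());
  std::copy(y.begin(), y.end(), y0.begin());
  // whiten X and y jointly via Levinson-Durbin (no materialized W matrix)
  std::vector<double> a(n, 0.0), a_prev(n, 0.0);
  std::vector<double> wy(n), wx(static_cast<size_t>(n) * p);
  double v = 1.0, logdet = 0.0;
  wy[0] = y0[0];
  for (int col = 0; col < p; ++col)
    wx[static_cast<size_t>(col) * n] = x0[static_cast<size_t>(col) * n];
  for (int m = 1; m < n; ++m) {
    double acc = r[m];
    for (int j = 1; j < m; ++j) acc -= a[j - 1] * r[m - j];
    double k = acc / v;
    for (int j = 0; j < m; ++j) a_prev[j] = a[j];
    for (int j = 1; j < m; ++j) a[j - 1] = a_prev[j - 1] - k * a_prev[m - j - 1];
    a[m - 1] = k;
    v *= (1.0 - k * k);
    if (!(v > 1e-300)) return R_NegInf;
    logdet += std::log(v);
    double sv = std::sqrt(v);
    double pred = 0.0;
    for (int j = 1; j <= m; ++j) pred += a[j - 1] * y0[m - j];
    wy[m] = (y0[m] - pred) / sv;
    for (int col = 0; col < p; ++col) {
      const double* xc0 = &x0[static_cast<size_t>(col) * n];
      double* xc = &wx[static_cast<size_t>(col) * n];
      pred = 0.0;
      for (int j = 1; j <= m; ++j) pred += a[j - 1] * xc0[m - j];
      xc[m] = (xc0[m] - pred) / sv;
    }
  }
  // normal equations G beta = g on whitened data; Cholesky, p is small
  std::vector<double> G(static_cast<size_t>(p) * p, 0.0), g(p, 0.0), beta(p);
  for (int i = 0; i < p; ++i) {
    const double* xi = &wx[static_cast<size_t>(i) * n];
    for (int j = i; j < p; ++j) {
      const double* xj = &wx[static_cast<size_t>(j) * n];
      double s = 0.0;
      for (int t = 0; t < n; ++t) s += xi[t] * xj[t];
      G[i * p + j] = s;
      G[j * p + i] = s;
    }
    double s = 0.0;
    for (int t = 0; t < n; ++t) s += xi[t] * wy[t];
    g[i] = s;
  }
  // in-place Cholesky G = LL'
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = G[i * p + j];
      for (int k2 = 0; k2 < j; ++k2) s -= G[i * p + k2] * G[j * p + k2];
      if (i == j) {
        if (s <= 0.0) return R_NegInf;
        G[i * p + j] = std::sqrt(s);
      } else {
        G[i * p + j] = s / G[j * p + j];
      }
    }
  }
  // solve L z = g, L' beta = z
  for (int i = 0; i < p; ++i) {
    double s = g[i];
    for (int j = 0; j < i; ++j) s -= G[i * p + j] * beta[j];
    beta[i] = s / G[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = beta[i];
    for (int j = i + 1; j < p; ++j) s -= G[j * p + i] * beta[j];
    beta[i] = s / G[i * p + i];
  }
  double rss = 0.0;
  for (int t = 0; t < n; ++t) {
    double fit = 0.0;
    for (int col = 0; col < p; ++col) fit += wx[static_cast<size_t>(col) * n + t] * beta[col];
    double e = wy[t] - fit;
    rss += e * e;
  }
  if (!(rss > 0.0)) rss = 1e-300; // exact fit: likelihood unbounded, clamp
  double sigma2 = rss / n;
  return -0.5 * n * std::log(2.0 * M_PI * sigma2) - 0.5 * logdet - 0.5 * n;
}
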