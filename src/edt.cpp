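#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean squared distance transform (Felzenszwalb & Huttenlocher,
// separable lower-envelope-of-parabolas), with per-axis physical spacing.
// Input: logical feature mask; output: per voxel, squared mm distance to the
// nearest feature voxel centre (0 inside features).

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(std::vector<double> &f, double w2, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  int n = f.size();
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[kk]] == INF) { v[kk] = q; z[kk] = -INF; z[kk + 1] = INF; continue; }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[kk]] + w2 * v[kk] * v[kk])) /
          (2.0 * w2 * (q - v[kk]));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[kk + 1] < q) ++kk;
    double dq = (double)(q - v[kk]);
    d[q] = w2 * dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      size_t base = (size_t)n1 * (j + (size_t)n2 * k);
      f.assign(g.begin() + base, g.begin() + base + n1);
      dt1d(f, w2, d, v, z);
      for (int i = 0; i < n1; ++i) g[base + i] = d[i];
    }
  // axis 2
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j)
        f[j] = g[i + (size_t)n1 * (j + (size_t)n2 * k)];
      f.resize(n2);
      dt1d(f, w2, d, v, z);
      for (int j = 0; j < n2; ++j)
        g[i + (size_t)n1 * (j + (size_t)n2 * k)] = d[j];
      f.resize(nmax);
    }
  // axis 3
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k)
        f[k] = g[i + (size_t)n1 * (j + (size_t)n2 * k)];
      f.resize(n3);
      dt1d(f, w2, d, v, z);
      for (int k = 0; k < n3; ++k)
        g[i + (size_t)n1 * (j + (size_t)n2 * k)] = d[k];
      f.resize(nmax);
    }

  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}
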