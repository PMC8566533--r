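#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Gray levels are stored as a full 3D integer array with 0 outside the mask
// and values in [1, ng] inside. All neighbourhoods are 3D 26-connectivity;
// GLCM uses the 13 unique direction vectors (offset and its negation merged
// by symmetric accumulation).

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  // 13 unique offsets: first nonzero component positive in (dk, dj, di) order
  int offs[13][3];
  int cnt = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if (dk > 0 || (dk == 0 && dj > 0) || (dk == 0 && dj == 0 && di > 0)) {
          offs[cnt][0] = di; offs[cnt][1] = dj; offs[cnt][2] = dk; ++cnt;
        }
      }
  NumericMatrix P(ng, ng);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = levels[idx3(i, j, k, n1, n2)];
        if (a <= 0) continue;
        for (int o = 0; o < 13; ++o) {
          int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          int b = levels[idx3(ii, jj, kk, n1, n2)];
          if (b <= 0) continue;
          P(a - 1, b - 1) += 1.0;
          P(b - 1, a - 1) += 1.0;
        }
      }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int ng,
                       int alpha) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericMatrix P(ng, 27); // dependence d in [0, 26], column d + 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = levels[idx3(i, j, k, n1, n2)];
        if (a <= 0) continue;
        int d = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
                continue;
              int b = levels[idx3(ii, jj, kk, n1, n2)];
              if (b <= 0) continue;
              if (std::abs(a - b) <= alpha) ++d;
            }
        P(a - 1, d) += 1.0;
      }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones; // (level, size)
  std::vector<int> stack;
  int smax = 1;
  for (int s0 = 0; s0 < n; ++s0) {
    if (seen[s0] || levels[s0] <= 0) continue;
    int lev = levels[s0];
    int size = 0;
    stack.clear();
    stack.push_back(s0);
    seen[s0] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int k = cur / (n1 * n2);
      int rem = cur % (n1 * n2);
      int j = rem / n1;
      int i = rem % n1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
              continue;
            int nb = idx3(ii, jj, kk, n1, n2);
            if (!seen[nb] && levels[nb] == lev) {
              seen[nb] = 1;
              stack.push_back(nb);
            }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > smax) smax = size;
  }
  NumericMatrix P(ng, smax);
  for (size_t z = 0; z < zones.size(); ++z)
    P(zones[z].first - 1, zones[z].second - 1) += 1.0;
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericMatrix P(ng, 2); // columns: n_i, s_i
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = levels[idx3(i, j, k, n1, n2)];
        if (a <= 0) continue;
        double sum = 0.0;
        int nn = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
                continue;
              int b = levels[idx3(ii, jj, kk, n1, n2)];
              if (b <= 0) continue;
              sum += b;
              ++nn;
            }
        if (nn == 0) continue; // isolated voxel: no neighbourhood difference
        P(a - 1, 0) += 1.0;
        P(a - 1, 1) += std::fabs((double)a - sum / nn);
      }
  return P;
}
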