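#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Iso-surface of a binary mask at level 0.5 by tetrahedral-decomposition
// marching (marching tetrahedra): each grid cell is split into six
// tetrahedra around its main diagonal; surface vertices sit at midpoints of
// edges joining an inside and an outside corner. The caller pads the mask
// with a zero layer so the surface is closed. Triangles are oriented
// outward (checked against the inside/outside corner centroids), so the
// divergence-theorem volume is the enclosed volume.

struct Key {
  long long a, b, c;
  bool operator==(const Key &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};
struct KeyHash {
  size_t operator()(const Key &k) const {
    return std::hash<long long>()(k.a * 73856093LL ^ k.b * 19349663LL ^
                                  k.c * 83492791LL);
  }
};

// [[Rcpp::export]]
List cpp_mesh(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  auto at = [&](int i, int j, int k) -> bool {
    return mask[i + (size_t)n1 * (j + (size_t)n2 * k)];
  };
  // corner offsets around main diagonal p0 -> p6
  static const int corner[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  std::unordered_map<Key, int, KeyHash> vindex;
  std::vector<double> vx, vy, vz; // unique vertices (index-space * 2)
  std::vector<int> tri;           // triangle vertex indices
  double area = 0.0, vol6 = 0.0;

  // midpoint vertex between two corners, deduplicated on doubled coords
  auto midv = [&](const double a[3], const double b[3]) -> int {
    Key key;
    key.a = (long long)std::llround(a[0] + b[0]);
    key.b = (long long)std::llround(a[1] + b[1]);
    key.c = (long long)std::llround(a[2] + b[2]);
    auto it = vindex.find(key);
    if (it != vindex.end()) return it->second;
    int id = vx.size();
    vindex[key] = id;
    vx.push_back(key.a);
    vy.push_back(key.b);
    vz.push_back(key.c);
    return id;
  };

  auto emit = [&](int a, int b, int c, const double in_c[3],
                  const double out_c[3]) {
    double p0[3] = {vx[a] * 0.25 * spacing[0], vy[a] * 0.25 * spacing[1],
                    vz[a] * 0.25 * spacing[2]};
    double p1[3] = {vx[b] * 0.25 * spacing[0], vy[b] * 0.25 * spacing[1],
                    vz[b] * 0.25 * spacing[2]};
    double p2[3] = {vx[c] * 0.25 * spacing[0], vy[c] * 0.25 * spacing[1],
                    vz[c] * 0.25 * spacing[2]};
    double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double nx = u[1] * w[2] - u[2] * w[1];
    double ny = u[2] * w[0] - u[0] * w[2];
    double nz = u[0] * w[1] - u[1] * w[0];
    // orient outward: normal should point from inside centroid to outside
    double dx = (out_c[0] - in_c[0]) * spacing[0];
    double dy = (out_c[1] - in_c[1]) * spacing[1];
    double dz = (out_c[2] - in_c[2]) * spacing[2];
    if (nx * dx + ny * dy + nz * dz < 0) {
      int tmp = b; b = c; c = tmp;
      nx = -nx; ny = -ny; nz = -nz;
      double sw[3] = {p1[0], p1[1], p1[2]};
      p1[0] = p2[0]; p1[1] = p2[1]; p1[2] = p2[2];
      p2[0] = sw[0]; p2[1] = sw[1]; p2[2] = sw[2];
    }
    area += 0.5 * std::sqrt(nx * nx + ny * ny + nz * nz);
    vol6 += p0[0] * (p1[1] * p2[2] - p1[2] * p2[1]) -
            p0[1] * (p1[0] * p2[2] - p1[2] * p2[0]) +
            p0[2] * (p1[0] * p2[1] - p1[1] * p2[0]);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  };

  for (int k = 0; k < n3 - 1; ++k)
    for (int j = 0; j < n2 - 1; ++j)
      for (int i = 0; i < n1 - 1; ++i) {
        bool in[8];
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          in[c] = at(i + corner[c][0], j + corner[c][1], k + corner[c][2]);
          nin += in[c];
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          double P[4][3];
          bool tin[4];
          int cnt = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = tets[t][c];
            P[c][0] = 2.0 * (i + corner[cc][0]);
            P[c][1] = 2.0 * (j + corner[cc][1]);
            P[c][2] = 2.0 * (k + corner[cc][2]);
            tin[c] = in[cc];
            cnt += tin[c];
          }
          if (cnt == 0 || cnt == 4) continue;
          // centroids of inside and outside corners (index-space * 2)
          double ic[3] = {0, 0, 0}, oc[3] = {0, 0, 0};
          for (int c = 0; c < 4; ++c)
            for (int d = 0; d < 3; ++d)
              (tin[c] ? ic : oc)[d] += P[c][d];
          for (int d = 0; d < 3; ++d) {
            ic[d] /= 2.0 * cnt;      // halve back to index space
            oc[d] /= 2.0 * (4 - cnt);
          }
          if (cnt == 1 || cnt == 3) {
            bool want = (cnt == 1);
            int apex = -1, others[3], no = 0;
            for (int c = 0; c < 4; ++c) {
              if (tin[c] == want) apex = c; else others[no++] = c;
            }
            int a = midv(P[apex], P[others[0]]);
            int b = midv(P[apex], P[others[1]]);
            int c2 = midv(P[apex], P[others[2]]);
            emit(a, b, c2, ic, oc);
          } else { // cnt == 2
            int A = -1, B = -1, C = -1, D = -1;
            for (int c = 0; c < 4; ++c) {
              if (tin[c]) { if (A < 0) A = c; else B = c; }
              else { if (C < 0) C = c; else D = c; }
            }
            int m1 = midv(P[A], P[C]);
            int m2 = midv(P[A], P[D]);
            int m3 = midv(P[B], P[D]);
            int m4 = midv(P[B], P[C]);
            emit(m1, m2, m3, ic, oc);
            emit(m1, m3, m4, ic, oc);
          }
        }
      }

  int nv = vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i] * 0.25 * spacing[0];
    V(i, 1) = vy[i] * 0.25 * spacing[1];
    V(i, 2) = vz[i] * 0.25 * spacing[2];
  }
  return List::create(Named("area") = area,
                      Named("volume") = std::fabs(vol6) / 6.0,
                      Named("vertices") = V,
                      Named("ntriangles") = (int)(tri.size() / 3));
}

// Max pairwise distances of a vertex cloud: full 3D and the three
// axis-dropped 2D projections (columns dropped: 3 = slice plane, etc.).
// [[Rcpp::export]]
NumericVector cpp_diameters(NumericMatrix V) {
  int n = V.nrow();
  double d3 = 0, d12 = 0, d13 = 0, d23 = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = V(i, 0) - V(j, 0);
      double dy = V(i, 1) - V(j, 1);
      double dz = V(i, 2) - V(j, 2);
      double a = dx * dx + dy * dy, b = dx * dx + dz * dz,
             c = dy * dy + dz * dz;
      double f = a + dz * dz;
      if (f > d3) d3 = f;
      if (a > d12) d12 = a;
      if (b > d13) d13 = b;
      if (c > d23) d23 = c;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(d12),
                               std::sqrt(d13), std::sqrt(d23));
}
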