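#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Euclidean k-NN vote fractions. Neighbour ties in distance are broken by
// training-point index (stable sort on (distance, index)) so predictions
// are reproducible.

static void knn_votes_raw(const std::vector<double> &tr, int ntr, int p,
                          const std::vector<int> &y,
                          const std::vector<double> &te, int nte, int k,
                          std::vector<double> &out) {
  std::vector<std::pair<double, int> > d(ntr);
  for (int t = 0; t < nte; ++t) {
    for (int r = 0; r < ntr; ++r) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        double diff = tr[r + (size_t)ntr * c] - te[t + (size_t)nte * c];
        s += diff * diff;
      }
      d[r] = std::make_pair(s, r);
    }
    int kk = k < ntr ? k : ntr;
    std::partial_sort(d.begin(), d.begin() + kk, d.end());
    int pos = 0;
    for (int r = 0; r < kk; ++r) pos += y[d[r].second];
    out[t] = (double)pos / kk;
  }
}

// [[Rcpp::export]]
NumericVector cpp_knn_vote(NumericMatrix train, IntegerVector y,
                           NumericMatrix test, int k) {
  int ntr = train.nrow(), p = train.ncol(), nte = test.nrow();
  std::vector<double> tr(train.begin(), train.end());
  std::vector<double> te(test.begin(), test.end());
  std::vector<int> yy(y.begin(), y.end());
  std::vector<double> out(nte);
  knn_votes_raw(tr, ntr, p, yy, te, nte, k, out);
  return wrap(out);
}

static double midrank_auc(const std::vector<double> &score,
                          const std::vector<int> &y) {
  int n = score.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return score[a] < score[b];
  });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && score[ord[j + 1]] == score[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0; // midrank, 1-based
    for (int t = i; t <= j; ++t) rank[ord[t]] = r;
    i = j + 1;
  }
  double rsum = 0.0;
  int n1 = 0;
  for (int t = 0; t < n; ++t)
    if (y[t] == 1) { rsum += rank[t]; ++n1; }
  int n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rsum - n1 * (n1 + 1.0) / 2.0) / ((double)n1 * n0);
}

// [[Rcpp::export]]
double cpp_auc(NumericVector score, IntegerVector y) {
  std::vector<double> s(score.begin(), score.end());
  std::vector<int> yy(y.begin(), y.end());
  return midrank_auc(s, yy);
}

// Cross-validated k-NN AUC within one balanced subset: for each fold,
// standardize features with the training folds' mean/sd, score validation
// lesions by neighbour vote fraction, compute the fold AUC; return the mean
// over usable folds (folds whose train or validation part is single-class
// are skipped). Returns NA if no fold is usable.
// [[Rcpp::export]]
double cpp_cv_auc(NumericMatrix X, IntegerVector y, IntegerVector fold,
                  int k, int nfold) {
  int n = X.nrow(), p = X.ncol();
  double accum = 0.0;
  int used = 0;
  for (int f = 1; f <= nfold; ++f) {
    std::vector<int> tri, tei;
    for (int i = 0; i < n; ++i)
      (fold[i] == f ? tei : tri).push_back(i);
    if (tri.empty() || tei.empty()) continue;
    int pos_tr = 0, pos_te = 0;
    for (size_t i = 0; i < tri.size(); ++i) pos_tr += y[tri[i]];
    for (size_t i = 0; i < tei.size(); ++i) pos_te += y[tei[i]];
    if (pos_tr == 0 || pos_tr == (int)tri.size()) continue;
    if (pos_te == 0 || pos_te == (int)tei.size()) continue;
    // column stats on training part
    std::vector<double> mu(p, 0.0), sd(p, 0.0);
    int ntr = tri.size(), nte = tei.size();
    for (int c = 0; c < p; ++c) {
      double s = 0.0;
      for (int i = 0; i < ntr; ++i) s += X(tri[i], c);
      mu[c] = s / ntr;
      double v = 0.0;
      for (int i = 0; i < ntr; ++i) {
        double dv = X(tri[i], c) - mu[c];
        v += dv * dv;
      }
      sd[c] = ntr > 1 ? std::sqrt(v / (ntr - 1)) : 0.0;
      if (sd[c] <= 0.0) sd[c] = 1.0;
    }
    std::vector<double> tr((size_t)ntr * p), te((size_t)nte * p);
    std::vector<int> ytr(ntr), yte(nte);
    for (int c = 0; c < p; ++c) {
      for (int i = 0; i < ntr; ++i)
        tr[i + (size_t)ntr * c] = (X(tri[i], c) - mu[c]) / sd[c];
      for (int i = 0; i < nte; ++i)
        te[i + (size_t)nte * c] = (X(tei[i], c) - mu[c]) / sd[c];
    }
    for (int i = 0; i < ntr; ++i) ytr[i] = y[tri[i]];
    for (int i = 0; i < nte; ++i) yte[i] = y[tei[i]];
    std::vector<double> votes(nte);
    knn_votes_raw(tr, ntr, p, ytr, te, nte, k, votes);
    double a = midrank_auc(votes, yte);
    if (!ISNA(a)) { accum += a; ++used; }
  }
  if (used == 0) return NA_REAL;
  return accum / used;
}

// Mean cross-validated AUC over many balanced subsets: `subsets` and
// `folds` are parallel lists of 0-based row indices into X and per-lesion
// fold labels. Subsets with no usable fold are dropped.
// [[Rcpp::export]]
double cpp_cv_auc_mean(NumericMatrix X, IntegerVector y, List subsets,
                       List folds, int k, int nfold) {
  int p = X.ncol();
  double accum = 0.0;
  int used = 0;
  for (int s = 0; s < subsets.size(); ++s) {
    IntegerVector idx = subsets[s];
    IntegerVector fo = folds[s];
    int n = idx.size();
    NumericMatrix Xs(n, p);
    IntegerVector ys(n);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < p; ++c) Xs(i, c) = X(idx[i], c);
      ys[i] = y[idx[i]];
    }
    double a = cpp_cv_auc(Xs, ys, fo, k, nfold);
    if (!ISNA(a)) { accum += a; ++used; }
  }
  if (used == 0) return NA_REAL;
  return accum / used;
}

// Per-subset cross-validated AUCs (NA where a subset has no usable fold).
// [[Rcpp::export]]
NumericVector cpp_cv_auc_persubset(NumericMatrix X, IntegerVector y,
                                   List subsets, List folds, int k,
                                   int nfold) {
  int p = X.ncol();
  NumericVector out(subsets.size());
  for (int s = 0; s < subsets.size(); ++s) {
    IntegerVector idx = subsets[s];
    IntegerVector fo = folds[s];
    int n = idx.size();
    NumericMatrix Xs(n, p);
    IntegerVector ys(n);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < p; ++c) Xs(i, c) = X(idx[i], c);
      ys[i] = y[idx[i]];
    }
    out[s] = cpp_cv_auc(Xs, ys, fo, k, nfold);
  }
  return out;
}
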