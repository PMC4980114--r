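#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-wise Spearman preparation: average ranks (ties share the mean
// rank), centred and scaled to unit norm so that the cross-product of two
// prepared vectors is their Spearman rho. Columns containing NA, or with
// zero rank variance (constant input), come back all-NA.
// [[Rcpp::export(name = ".std_rank_cols")]]
NumericMatrix std_rank_cols(NumericMatrix V) {
  const int n = V.nrow(), k = V.ncol();
  NumericMatrix Z(n, k);
  std::vector<int> idx(n);
  std::vector<double> r(n), col(n);
  const double *vp = REAL(V);
  for (int j = 0; j < k; ++j) {
    const double *cj = vp + (size_t)j * n;
    bool has_na = false;
    for (int i = 0; i < n; ++i) {
      col[i] = cj[i];
      if (ISNAN(cj[i])) { has_na = true; break; }
    }
    if (has_na) {
      for (int i = 0; i < n; ++i) Z(i, j) = NA_REAL;
      continue;
    }
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < n) {                       // average ranks over tie runs
      int e = i;
      while (e + 1 < n && col[idx[e + 1]] == col[idx[i]]) ++e;
      const double avg = 0.5 * (i + e) + 1.0;
      for (int t = i; t <= e; ++t) r[idx[t]] = avg;
      i = e + 1;
    }
    const double mean = (n + 1) / 2.0;    // mean rank, ties included
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      const double d = r[t] - mean;
      ss += d * d;
    }
    if (ss == 0.0) {
      for (int t = 0; t < n; ++t) Z(t, j) = NA_REAL;
      continue;
    }
    const double s = std::sqrt(ss);
    for (int t = 0; t < n; ++t) Z(t, j) = (r[t] - mean) / s;
  }
  return Z;
}

// Sliding-window variant of the Spearman preparation: patterns are the
// vectorized freq x (2h+1) windows of P centred on `centres` (0-based time
// column indices). Consecutive centres shift the window by one column, so
// the sorted order is maintained incrementally (drop one column, merge one
// column) instead of re-sorting the full pattern at every centre. Windows
// touching an NA column (or the matrix edge) give all-NA output columns.
// Output columns are the standardized average ranks in pattern layout
// (frequency fastest, window time second), matching .std_rank_cols.
// [[Rcpp::export(name = ".std_rank_windows")]]
NumericMatrix std_rank_windows(NumericMatrix P, IntegerVector centres,
                               int h) {
  const int nf = P.nrow(), nt = P.ncol(), nc = centres.size();
  const int nw = 2 * h + 1, n = nf * nw;
  NumericMatrix Z(n, nc);
  const double *pp = REAL(P);
  std::vector<char> colna(nt, 0);
  for (int t = 0; t < nt; ++t) {
    const double *c = pp + (size_t)t * nf;
    for (int i = 0; i < nf; ++i)
      if (ISNAN(c[i])) { colna[t] = 1; break; }
  }
  struct El { double v; int col; int f; };
  auto cmp = [](const El &x, const El &y) { return x.v < y.v; };
  std::vector<El> a, tmp, add;
  a.reserve(n); tmp.reserve(n); add.reserve(nf);
  std::vector<double> rnk(n);
  int prev = -2;
  bool have = false;
  const double mean = (n + 1) / 2.0;
  for (int ci = 0; ci < nc; ++ci) {
    const int c = centres[ci];
    bool bad = (c - h < 0) || (c + h >= nt);
    if (!bad)
      for (int t = c - h; t <= c + h; ++t)
        if (colna[t]) { bad = true; break; }
    if (bad) {
      for (int i = 0; i < n; ++i) Z(i, ci) = NA_REAL;
      have = false; prev = c;
      continue;
    }
    if (have && c == prev + 1) {
      const int dropc = prev - h, addc = c + h;
      size_t w = 0;
      for (size_t i = 0; i < a.size(); ++i)
        if (a[i].col != dropc) a[w++] = a[i];
      a.resize(w);
      add.clear();
      const double *cc = pp + (size_t)addc * nf;
      for (int f = 0; f < nf; ++f) add.push_back(El{cc[f], addc, f});
      std::sort(add.begin(), add.end(), cmp);
      tmp.clear();
      std::merge(a.begin(), a.end(), add.begin(), add.end(),
                 std::back_inserter(tmp), cmp);
      a.swap(tmp);
    } else {
      a.clear();
      for (int t = c - h; t <= c + h; ++t) {
        const double *cc = pp + (size_t)t * nf;
        for (int f = 0; f < nf; ++f) a.push_back(El{cc[f], t, f});
      }
      std::sort(a.begin(), a.end(), cmp);
      have = true;
    }
    prev = c;
    int i = 0;
    while (i < n) {                       // tie-averaged ranks
      int e = i;
      while (e + 1 < n && a[e + 1].v == a[i].v) ++e;
      const double avg = 0.5 * (i + e) + 1.0;
      for (int t = i; t <= e; ++t)
        rnk[(size_t)(a[t].col - (c - h)) * nf + a[t].f] = avg;
      i = e + 1;
    }
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      const double d = rnk[t] - mean;
      ss += d * d;
    }
    if (ss == 0.0) {
      for (int t = 0; t < n; ++t) Z(t, ci) = NA_REAL;
      continue;
    }
    const double s = std::sqrt(ss);
    for (int t = 0; t < n; ++t) Z(t, ci) = (rnk[t] - mean) / s;
  }
  return Z;
}
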