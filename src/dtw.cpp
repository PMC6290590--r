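#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Banded DTW with absolute-difference local cost and the symmetric
// match/insert/delete step pattern; accumulated cost is NOT normalized.
// `band` is the Sakoe-Chiba half-width in samples; cells with |i-j| > band
// are forbidden.  `abandon_above`: return +Inf as soon as the row-wise
// minimum of the cumulative cost exceeds it (every warping path visits
// every row, and cumulative cost is nondecreasing along a path, so the
// row minimum is a valid lower bound on the final cost).
static double dtw_band(const double* a, int n, const double* b, int m,
                       int band, double abandon_above) {
  if (std::abs(n - m) > band) return INF;  // caller validates; safety net
  std::vector<double> buf0(m, INF), buf1(m, INF);
  double* prev = buf0.data();
  double* cur = buf1.data();
  // row 0: only horizontal moves
  {
    int hi = std::min(m - 1, band);
    double acc = 0.0;
    for (int j = 0; j <= hi; ++j) {
      acc += std::fabs(a[0] - b[j]);
      prev[j] = acc;
    }
    if (hi + 1 < m) prev[hi + 1] = INF;
    if (n == 1) return prev[m - 1];
  }
  for (int i = 1; i < n; ++i) {
    int lo = std::max(0, i - band);
    int hi = std::min(m - 1, i + band);
    // sentinel writes: the row buffers alternate, so the cells just
    // outside this row's band would otherwise hold values from row i-2
    if (lo > 0) cur[lo - 1] = INF;
    if (hi + 1 < m) cur[hi + 1] = INF;
    double rowmin;
    {
      int j = lo;
      double best = prev[j];
      if (j > 0) {
        best = std::min(best, prev[j - 1]);
        best = std::min(best, cur[j - 1]);
      }
      double c = best + std::fabs(a[i] - b[j]);
      cur[j] = c;
      rowmin = c;
    }
    for (int j = lo + 1; j <= hi; ++j) {
      double best = std::min(prev[j],
                             std::min(prev[j - 1], cur[j - 1]));
      double c = best + std::fabs(a[i] - b[j]);
      cur[j] = c;
      if (c < rowmin) rowmin = c;
    }
    if (rowmin > abandon_above) return INF;
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Upper/lower running envelope of a sequence over a +-band window,
// feeding the LB_Keogh lower bound.
static void envelope(const double* x, int n, int band,
                     double* up, double* lo) {
  for (int t = 0; t < n; ++t) {
    int a = std::max(0, t - band);
    int b = std::min(n - 1, t + band);
    double u = x[a], l = x[a];
    for (int s = a + 1; s <= b; ++s) {
      if (x[s] > u) u = x[s];
      if (x[s] < l) l = x[s];
    }
    up[t] = u;
    lo[t] = l;
  }
}

// LB_Keogh: for any banded warping path, each x[t] is matched to some
// c[s] with |t-s| <= band, so |x[t]-c[s]| >= max(0, x[t]-U[t], L[t]-x[t]).
// Summing gives a valid lower bound on the banded DTW distance with
// absolute local cost. Early-exits once `stop_above` is exceeded.
static double lb_keogh(const double* x, const double* up,
                       const double* lo, int n, double stop_above) {
  double s = 0.0;
  for (int t = 0; t < n; ++t) {
    double v = x[t];
    if (v > up[t]) s += v - up[t];
    else if (v < lo[t]) s += lo[t] - v;
    if (s > stop_above) return s;
  }
  return s;
}

// [[Rcpp::export]]
double cpp_dtw(NumericVector a, NumericVector b, int band) {
  if (a.size() == 0 || b.size() == 0) stop("empty sequence");
  if (std::abs((int)a.size() - (int)b.size()) > band)
    stop("band infeasible for length difference");
  return dtw_band(a.begin(), a.size(), b.begin(), b.size(), band, INF);
}

// Full m x d matrix of DTW distances between rows of X and rows of C.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_matrix(NumericMatrix X, NumericMatrix C, int band) {
  int m = X.nrow(), d = C.nrow(), L = X.ncol(), Lc = C.ncol();
  if (std::abs(L - Lc) > band) stop("band infeasible for length difference");
  NumericMatrix out(m, d);
  std::vector<double> x(L), c(Lc);
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < L; ++t) x[t] = X(i, t);
    for (int k = 0; k < d; ++k) {
      for (int t = 0; t < Lc; ++t) c[t] = C(k, t);
      out(i, k) = dtw_band(x.data(), L, c.data(), Lc, band, INF);
    }
  }
  return out;
}

// Nearest atom (row of C) for each row of X under banded DTW, with exact
// pruning: an atom is skipped or abandoned only when a lower bound on its
// distance (LB_Keogh on the atom's envelope, then the row-minimum bound
// inside the DP) strictly exceeds the best distance so far, so the result
// is identical to the argmin of the full distance matrix (ties -> lowest
// atom index).  Atoms are tried in ascending order of the diagonal-path
// upper bound sum|x - c| to tighten the threshold early.
// [[Rcpp::export]]
List cpp_dtw_nearest(NumericMatrix X, NumericMatrix C, int band) {
  int m = X.nrow(), d = C.nrow(), L = X.ncol(), Lc = C.ncol();
  if (L != Lc) stop("subsequence and atom lengths differ");
  IntegerVector idx(m);
  NumericVector dist(m);
  std::vector<double> x(L), ub(d);
  std::vector<int> ord(d);
  std::vector<std::vector<double>> atoms(d, std::vector<double>(L)),
      aup(d, std::vector<double>(L)), alo(d, std::vector<double>(L));
  for (int k = 0; k < d; ++k) {
    for (int t = 0; t < L; ++t) atoms[k][t] = C(k, t);
    envelope(atoms[k].data(), L, band, aup[k].data(), alo[k].data());
  }
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < L; ++t) x[t] = X(i, t);
    for (int k = 0; k < d; ++k) {
      double s = 0.0;
      for (int t = 0; t < L; ++t) s += std::fabs(x[t] - atoms[k][t]);
      ub[k] = s;
      ord[k] = k;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int u, int v) { return ub[u] < ub[v] || (ub[u] == ub[v] && u < v); });
    double best = INF;
    int besti = -1;
    for (int r = 0; r < d; ++r) {
      int k = ord[r];
      if (best < INF &&
          lb_keogh(x.data(), aup[k].data(), alo[k].data(), L, best) > best)
        continue;
      double dk = dtw_band(x.data(), L, atoms[k].data(), L, band, best);
      if (dk < best || (dk == best && k < besti)) {
        best = dk;
        besti = k;
      }
    }
    idx[i] = besti + 1;  // 1-based for R
    dist[i] = best;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Motif distance scores: rows of X are consecutive sliding subsequences of
// one series; start[j] is the start time (s).  D(j) = min DTW distance to
// any non-overlapping successor (start[j'] >= start[j] + k_sec), +Inf when
// no eligible successor exists.  LB_Keogh prefiltering and early
// abandoning against the running minimum keep the result exact.
// [[Rcpp::export]]
NumericVector cpp_distance_scores(NumericMatrix X, NumericVector start,
                                  double k_sec, int band) {
  int m = X.nrow(), L = X.ncol();
  NumericVector D(m);
  std::vector<std::vector<double>> rows(m, std::vector<double>(L)),
      rup(m, std::vector<double>(L)), rlo(m, std::vector<double>(L));
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < L; ++t) rows[i][t] = X(i, t);
    envelope(rows[i].data(), L, band, rup[i].data(), rlo[i].data());
  }
  for (int j = 0; j < m; ++j) {
    double best = INF;
    for (int j2 = j + 1; j2 < m; ++j2) {
      if (start[j2] < start[j] + k_sec) continue;
      if (best < INF &&
          lb_keogh(rows[j].data(), rup[j2].data(), rlo[j2].data(), L,
                   best) > best)
        continue;
      double dd = dtw_band(rows[j].data(), L, rows[j2].data(), L, band,
                           best);
      if (dd < best) best = dd;
    }
    D[j] = best;
  }
  return D;
}

// Direct-form II transposed IIR filter with initial state zi.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int n = b.size();          // == a.size(); a[0] == 1 assumed (normalized)
  int m = x.size();
  std::vector<double> z(zi.begin(), zi.end());
  z.resize(n - 1, 0.0);
  NumericVector y(m);
  for (int i = 0; i < m; ++i) {
    double yi = b[0] * x[i] + z[0];
    for (int k = 0; k < n - 2; ++k)
      z[k] = b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi;
    z[n - 2] = b[n - 1] * x[i] - a[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Symmetric pairwise DTW distance matrix between rows of X.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_pairwise(NumericMatrix X, int band) {
  int m = X.nrow(), L = X.ncol();
  NumericMatrix out(m, m);
  std::vector<std::vector<double>> rows(m, std::vector<double>(L));
  for (int i = 0; i < m; ++i)
    for (int t = 0; t < L; ++t) rows[i][t] = X(i, t);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double dd = dtw_band(rows[i].data(), L, rows[j].data(), L, band, INF);
      out(i, j) = dd;
      out(j, i) = dd;
    }
  }
  return out;
}
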