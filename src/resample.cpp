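#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mean expression profiles of sampled cell groups.
// X: cells x genes (dense); idx: n x size matrix of 1-based cell indices.
// Returns n x genes matrix of group means.
// [[Rcpp::export(name = ".profile_means_cpp")]]
NumericMatrix profile_means_cpp(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int n = idx.nrow(), size = idx.ncol(), G = X.ncol();
  const int nc = X.nrow();
  NumericMatrix P(n, G);
  // flatten indices once; iterate genes outermost so each X column (one
  // gene across cells) stays cache-resident while all groups accumulate
  std::vector<int> flat(static_cast<size_t>(n) * size);
  for (int s = 0; s < size; ++s)
    for (int i = 0; i < n; ++i) {
      const int c = idx(i, s) - 1;
      if (c < 0 || c >= nc) stop("cell index out of range");
      flat[static_cast<size_t>(s) * n + i] = c;
    }
  const double inv = 1.0 / size;
  for (int g = 0; g < G; ++g) {
    const double* xg = &X(0, g);
    double* pg = &P(0, g);
    for (int s = 0; s < size; ++s) {
      const int* cs = &flat[static_cast<size_t>(s) * n];
      for (int i = 0; i < n; ++i) pg[i] += xg[cs[i]];
    }
    for (int i = 0; i < n; ++i) pg[i] *= inv;
  }
  return P;
}

// average ranks (ties get the mean rank), as R's rank(x, ties.method="average")
static void rank_avg(const double* x, int G, std::vector<int>& ord,
                     std::vector<double>& r) {
  for (int g = 0; g < G; ++g) ord[g] = g;
  std::sort(ord.begin(), ord.end(),
            [x](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < G) {
    int j = i;
    while (j + 1 < G && x[ord[j + 1]] == x[ord[i]]) ++j;
    const double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
}

// Row-wise Spearman correlation between paired profile matrices (n x G).
// [[Rcpp::export(name = ".spearman_rows_cpp")]]
NumericVector spearman_rows_cpp(const NumericMatrix& P, const NumericMatrix& Q) {
  const int n = P.nrow(), G = P.ncol();
  if (Q.nrow() != n || Q.ncol() != G) stop("shape mismatch");
  NumericVector out(n);
  std::vector<int> ord(G);
  std::vector<double> rp(G), rq(G), xp(G), xq(G);
  for (int i = 0; i < n; ++i) {
    for (int g = 0; g < G; ++g) { xp[g] = P(i, g); xq[g] = Q(i, g); }
    rank_avg(xp.data(), G, ord, rp);
    rank_avg(xq.data(), G, ord, rq);
    double mp = 0, mq = 0;
    for (int g = 0; g < G; ++g) { mp += rp[g]; mq += rq[g]; }
    mp /= G; mq /= G;
    double sxy = 0, sxx = 0, syy = 0;
    for (int g = 0; g < G; ++g) {
      const double a = rp[g] - mp, b = rq[g] - mq;
      sxy += a * b; sxx += a * a; syy += b * b;
    }
    out[i] = (sxx > 0 && syy > 0) ? sxy / std::sqrt(sxx * syy) : NA_REAL;
  }
  return out;
}

// Normalized recovery-curve AUCs for each profile row and gene set.
// P: n x G profiles; columns must be ordered by gene id so that the
// descending-expression sort breaks ties toward the smaller gene id.
// sets: list of integer vectors of 1-based gene (column) indices.
// Window L may exceed G (the curve is flat past the end of the list).
// [[Rcpp::export(name = ".auc_rows_cpp")]]
NumericMatrix auc_rows_cpp(const NumericMatrix& P, const List& sets, int L) {
  const int n = P.nrow(), G = P.ncol(), S = sets.size();
  NumericMatrix A(n, S);
  std::vector<std::vector<int>> sidx(S);
  std::vector<double> denom(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector v = sets[s];
    sidx[s].assign(v.begin(), v.end());
    const double m = std::min<double>(v.size(), L);
    denom[s] = m * (m + 1) / 2.0 + m * (L - m);
  }
  std::vector<int> ord(G), pos(G);
  std::vector<double> x(G);
  for (int i = 0; i < n; ++i) {
    for (int g = 0; g < G; ++g) { x[g] = P(i, g); ord[g] = g; }
    std::stable_sort(ord.begin(), ord.end(), [&x](int a, int b) {
      return x[a] > x[b];  // stable: ties keep gene-id order
    });
    for (int r = 0; r < G; ++r) pos[ord[r]] = r + 1;
    for (int s = 0; s < S; ++s) {
      double raw = 0;
      for (int gi : sidx[s]) {
        const int r = pos[gi - 1];
        if (r <= L) raw += L - r + 1;
      }
      A(i, s) = denom[s] > 0 ? raw / denom[s] : 0.0;
    }
  }
  return A;
}
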