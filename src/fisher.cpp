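#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log choose from a cached log-factorial table
static inline double lchoose_t(const std::vector<double>& lf, int n, int k) {
  return lf[n] - lf[k] - lf[n - k];
}

// Two-sided Fisher exact p for [[a,b],[c,d]]: sum of hypergeometric
// probabilities <= p(observed) * (1 + 1e-7). Degenerate margins -> 1.
static double fisher_p(int a, int b, int c, int d,
                       const std::vector<double>& lf) {
  int m = a + b, n = c + d, k = a + c;
  if (m == 0 || n == 0 || k == 0 || k == m + n) return 1.0;
  int lo = std::max(0, k - n), hi = std::min(k, m);
  double lN = lchoose_t(lf, m + n, k);
  double lobs = lchoose_t(lf, m, a) + lchoose_t(lf, n, k - a) - lN;
  double thr = std::exp(lobs) * (1.0 + 1e-7);
  double s = 0.0;
  for (int x = lo; x <= hi; ++x) {
    double p = std::exp(lchoose_t(lf, m, x) + lchoose_t(lf, n, k - x) - lN);
    if (p <= thr) s += p;
  }
  return s < 1.0 ? s : 1.0;
}

static std::vector<double> lfact_table(int n) {
  std::vector<double> lf(n + 1);
  lf[0] = 0.0;
  for (int i = 1; i <= n; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  return lf;
}

// [[Rcpp::export]]
NumericVector fisher2x2_cpp(IntegerVector a, IntegerVector b,
                            IntegerVector c, IntegerVector d) {
  int n = a.size();
  int mx = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] < 0 || b[i] < 0 || c[i] < 0 || d[i] < 0)
      stop("all table entries must be non-negative");
    int t = a[i] + b[i] + c[i] + d[i];
    if (t > mx) mx = t;
  }
  std::vector<double> lf = lfact_table(mx + 1);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fisher_p(a[i], b[i], c[i], d[i], lf);
  return out;
}

// Per-site minimum pairwise Fisher p across T time points.
// meth/total: n_sites x T. A date enters a pair only if total >= min_cov.
// Returns n_sites x 2 matrix: [ p_min (NA if no testable pair), n_pairs ].
// [[Rcpp::export]]
NumericMatrix pmin_fisher_cpp(IntegerMatrix meth, IntegerMatrix total,
                              int min_cov) {
  int n = meth.nrow(), T = meth.ncol();
  if (total.nrow() != n || total.ncol() != T)
    stop("meth and total must have identical dimensions");
  int mx = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < T; ++j) {
      if (meth(i, j) < 0 || total(i, j) < meth(i, j))
        stop("counts must satisfy 0 <= meth <= total");
      // largest pair sum bounds the log-factorial table
    }
  for (int i = 0; i < n; ++i) {
    int t1 = 0, t2 = 0; // two largest totals in row
    for (int j = 0; j < T; ++j) {
      int t = total(i, j);
      if (t > t1) { t2 = t1; t1 = t; } else if (t > t2) t2 = t;
    }
    if (t1 + t2 > mx) mx = t1 + t2;
  }
  std::vector<double> lf = lfact_table(mx + 1);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double pmin = 2.0;
    int npairs = 0;
    for (int j = 0; j < T - 1; ++j) {
      int tj = total(i, j);
      if (tj < min_cov) continue;
      int mj = meth(i, j), uj = tj - mj;
      for (int k = j + 1; k < T; ++k) {
        int tk = total(i, k);
        if (tk < min_cov) continue;
        double p = fisher_p(mj, uj, meth(i, k), tk - meth(i, k), lf);
        if (p < pmin) pmin = p;
        ++npairs;
      }
    }
    out(i, 0) = npairs > 0 ? pmin : NA_REAL;
    out(i, 1) = npairs;
  }
  return out;
}
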