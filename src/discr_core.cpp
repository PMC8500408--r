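#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Tie-weighted discriminability counts.
//
// For every ordered within-item pair (j, j') and every measurement k of a
// different item, a violation is D(j,k) < D(j,j'), with an exact tie
// D(j,k) == D(j,j') counted as half a violation. Rows whose item has a
// single measurement get NA and contribute nothing.
//
// Per anchor row the across-item distances are sorted once and each
// within-item distance is located by binary search, so the cost per row is
// O(N log N) regardless of the replicate count.
//
// item: 0-based item index per row; rows: optional 0-based row subset of D
// (used by the permutation machinery to evaluate sub-designs of a stacked
// matrix without copying it).
// [[Rcpp::export(name = ".discr_counts")]]
List discr_counts(NumericMatrix D, IntegerVector item, Nullable<IntegerVector> rows = R_NilValue) {
  IntegerVector idx;
  if (rows.isNotNull()) {
    idx = IntegerVector(rows);
  } else {
    idx = seq(0, D.nrow() - 1);
  }
  const int N = idx.size();
  if (item.size() != N) stop("length(item) must match the number of rows in use");

  int nitem = 0;
  for (int j = 0; j < N; ++j) {
    if (item[j] == NA_INTEGER || item[j] < 0) stop("invalid item index");
    if (item[j] + 1 > nitem) nitem = item[j] + 1;
  }
  std::vector<int> gsize(nitem, 0);
  for (int j = 0; j < N; ++j) ++gsize[item[j]];

  NumericVector per(N, NA_REAL);
  double f = 0.0;
  double ncomp_total = 0.0;
  std::vector<double> across;
  across.reserve(N);

  for (int j = 0; j < N; ++j) {
    const int g = item[j];
    if (gsize[g] < 2) continue;
    const int rj = idx[j];
    across.clear();
    for (int k = 0; k < N; ++k) {
      if (item[k] != g) across.push_back(D(rj, idx[k]));
    }
    std::sort(across.begin(), across.end());
    const double m = static_cast<double>(across.size());
    double viol = 0.0;
    int npairs = 0;
    for (int jp = 0; jp < N; ++jp) {
      if (jp == j || item[jp] != g) continue;
      const double dw = D(rj, idx[jp]);
      const double nless = std::lower_bound(across.begin(), across.end(), dw) - across.begin();
      const double nleq  = std::upper_bound(across.begin(), across.end(), dw) - across.begin();
      viol += nless + 0.5 * (nleq - nless);
      ++npairs;
    }
    const double ncomp = npairs * m;
    per[j] = 1.0 - viol / ncomp;
    f += viol;
    ncomp_total += ncomp;
  }

  return List::create(_["per_measurement"] = per,
                      _["f"] = f,
                      _["n_comparisons"] = ncomp_total);
}

// Mean discriminability only (fast path for permutation loops).
// [[Rcpp::export(name = ".discr_mean")]]
double discr_mean(NumericMatrix D, IntegerVector item, Nullable<IntegerVector> rows = R_NilValue) {
  List res = discr_counts(D, item, rows);
  NumericVector per = res["per_measurement"];
  double s = 0.0; int n = 0;
  for (int j = 0; j < per.size(); ++j) {
    if (!NumericVector::is_na(per[j])) { s += per[j]; ++n; }
  }
  if (n == 0) return NA_REAL;
  return s / n;
}
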