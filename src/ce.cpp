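// Hot kernels of the combinatorial-extension style aligner: the O(nq*nt*L^2)
// fragment-pair window scan and the dynamic program chaining compatible
// fragment pairs into the best sequential alignment path.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All window pairs whose intra-fragment CA distance matrices agree to a mean
// absolute difference <= dIntra.  dq, dt are full CA-CA distance matrices;
// indices returned 0-based.
// [[Rcpp::export(name = ".afpScan")]]
List afpScan(NumericMatrix dq, NumericMatrix dt, int L, double dIntra) {
  const int nq = dq.nrow(), nt = dt.nrow();
  std::vector<int> qs, ts;
  std::vector<double> diffs;
  const double C = L * (L - 1) / 2.0;
  for (int i = 0; i + L <= nq; ++i) {
    for (int j = 0; j + L <= nt; ++j) {
      double s = 0.0;
      for (int a = 0; a < L - 1; ++a)
        for (int b = a + 1; b < L; ++b)
          s += std::fabs(dq(i + a, i + b) - dt(j + a, j + b));
      const double d = s / C;
      if (d <= dIntra) {
        qs.push_back(i);
        ts.push_back(j);
        diffs.push_back(d);
      }
    }
  }
  return List::create(_["qs"] = qs, _["ts"] = ts, _["diff"] = diffs);
}

// Chain AFPs into the best sequential path.  Input AFPs must be sorted by
// (qs, ts), 0-based.  Two AFPs p -> k are compatible when either they lie on
// the same diagonal and overlap (shift < L: their residue pairs are
// consistent), or both windows are disjoint with gaps <= gapMax in each chain
// and the cross-fragment mean distance difference <= dJoin.  Objective:
// maximise the number of aligned residue pairs, ties broken by the smaller
// sum of AFP differences, then by the earlier AFP.
// [[Rcpp::export(name = ".ceDp")]]
List ceDp(IntegerVector qs, IntegerVector ts, NumericVector diff,
          NumericMatrix dq, NumericMatrix dt, int L, double dJoin,
          int gapMax) {
  const int m = qs.size();
  if (m == 0)
    return List::create(_["path"] = IntegerVector(0),
                        _["pairs"] = IntegerMatrix(0, 2));
  std::vector<int> len(m), prev(m, -1);
  std::vector<double> cost(m);
  const int maxBack = L + gapMax;
  int lo = 0;
  int best = 0;
  for (int k = 0; k < m; ++k) {
    len[k] = L;
    cost[k] = diff[k];
    while (lo < k && qs[lo] < qs[k] - maxBack) ++lo;
    for (int p = lo; p < k; ++p) {
      if (qs[p] >= qs[k]) break;  // sorted: remaining share qs[k]
      const int s = qs[k] - qs[p];
      const int st = ts[k] - ts[p];
      if (st <= 0) continue;
      int add;
      if (s < L || st < L) {
        if (s != st || s >= L) continue;  // off-diagonal overlap: conflict
        add = s;                          // same-diagonal overlap
      } else {
        if (s - L > gapMax || st - L > gapMax) continue;
        double sum = 0.0;
        for (int a = 0; a < L; ++a)
          for (int b = 0; b < L; ++b)
            sum += std::fabs(dq(qs[p] + a, qs[k] + b) -
                             dt(ts[p] + a, ts[k] + b));
        if (sum / (L * L) > dJoin) continue;
        add = L;
      }
      const int nl = len[p] + add;
      const double nc = cost[p] + diff[k];
      if (nl > len[k] || (nl == len[k] && nc < cost[k] - 1e-12)) {
        len[k] = nl;
        cost[k] = nc;
        prev[k] = p;
      }
    }
    if (len[k] > len[best] ||
        (len[k] == len[best] && cost[k] < cost[best] - 1e-12))
      best = k;
  }
  std::vector<int> path;
  for (int k = best; k >= 0; k = prev[k]) path.push_back(k);
  std::reverse(path.begin(), path.end());
  std::vector<int> pq, pt;
  int lastQ = -1;
  for (size_t i = 0; i < path.size(); ++i) {
    const int k = path[i];
    for (int a = 0; a < L; ++a) {
      const int q = qs[k] + a;
      if (q > lastQ) {
        pq.push_back(q);
        pt.push_back(ts[k] + a);
        lastQ = q;
      }
    }
  }
  IntegerMatrix pairs(pq.size(), 2);
  for (size_t i = 0; i < pq.size(); ++i) {
    pairs(i, 0) = pq[i];
    pairs(i, 1) = pt[i];
  }
  IntegerVector pathOut(path.begin(), path.end());
  return List::create(_["path"] = pathOut, _["pairs"] = pairs);
}
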