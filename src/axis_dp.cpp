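#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dynamic program that partitions one axis into k = 1..kmax consecutive bins
// whose boundaries are restricted to `cand` (1-based positions in the target
// axis's sorted order, end-exclusive), maximizing the per-bin part of the
// trivariate mutual information decomposition
//
//   I(grid) = K + sum_t g(t),
//   g(t)    = sum_{ij} p(i,j,t) log2( p(i,t) p(j,t) / ( p(t) p(i,j,t) ) )
//
// where (i,j) are the cells of the two fixed partitions (K, the fixed-pair
// mutual information, does not depend on the target partition and is added
// by the caller).  Returns, for every k, max sum_t g(t) and the achieving
// cut positions.  Ties are broken toward earlier cuts (first maximum found
// scanning split points in increasing order), giving deterministic output.
//
// cellA, cellB: 1-based fixed-partition bin of each point, in target-sorted
// order; ni, nj: bin counts of the fixed partitions.

// [[Rcpp::export]]
List axis_dp_cpp(IntegerVector cellA, IntegerVector cellB, int ni, int nj,
                 IntegerVector cand, int kmax) {
  const int n = cellA.size();
  const int ncell = ni * nj;
  const int m = cand.size() + 1;           // number of atomic segments
  if (kmax > m) kmax = m;
  if (kmax < 1) kmax = 1;

  std::vector<int> ends(m);
  for (int s = 0; s < m - 1; ++s) ends[s] = cand[s];
  ends[m - 1] = n;

  // cumulative cell counts at segment ends: cum[e][c], e = 0..m
  std::vector<int> cum((m + 1) * ncell, 0);
  {
    int e = 1, pos = 0;
    std::vector<int> run(ncell, 0);
    for (; e <= m; ++e) {
      while (pos < ends[e - 1]) {
        run[(cellA[pos] - 1) * nj + (cellB[pos] - 1)]++;
        ++pos;
      }
      for (int c = 0; c < ncell; ++c) cum[e * ncell + c] = run[c];
    }
  }

  const double ln2 = std::log(2.0);
  // G[s*m + (e-1)] = g-sum of bin covering segments (s, e], 0 <= s < e <= m
  std::vector<double> G((size_t)m * m, 0.0);
  std::vector<int> cnt(ncell), ri(ni), qj(nj);
  for (int s = 0; s < m; ++s) {
    for (int e = s + 1; e <= m; ++e) {
      int C = 0;
      std::fill(ri.begin(), ri.end(), 0);
      std::fill(qj.begin(), qj.end(), 0);
      for (int c = 0; c < ncell; ++c) {
        int v = cum[e * ncell + c] - cum[s * ncell + c];
        cnt[c] = v;
        if (v) { ri[c / nj] += v; qj[c % nj] += v; C += v; }
      }
      double g = 0.0;
      if (C > 0) {
        const double logC = std::log((double)C);
        for (int c = 0; c < ncell; ++c) {
          int v = cnt[c];
          if (v)
            g += v * (std::log((double)ri[c / nj]) + std::log((double)qj[c % nj])
                      - logC - std::log((double)v));
        }
        g /= (double)n * ln2;               // bits, probability-weighted
      }
      G[(size_t)s * m + (e - 1)] = g;
    }
  }

  const double NEG = -1e300;
  // F[k][e]: best g-sum using exactly k bins covering segments 1..e
  std::vector<double> F((size_t)(kmax + 1) * (m + 1), NEG);
  std::vector<int> bp((size_t)(kmax + 1) * (m + 1), -1);
  for (int e = 1; e <= m; ++e) F[1 * (m + 1) + e] = G[0 * m + (e - 1)];
  for (int k = 2; k <= kmax; ++k) {
    for (int e = k; e <= m; ++e) {
      double best = NEG; int barg = -1;
      for (int s = k - 1; s < e; ++s) {
        double prev = F[(size_t)(k - 1) * (m + 1) + s];
        if (prev <= NEG) continue;
        double v = prev + G[(size_t)s * m + (e - 1)];
        if (v > best) { best = v; barg = s; }
      }
      F[(size_t)k * (m + 1) + e] = best;
      bp[(size_t)k * (m + 1) + e] = barg;
    }
  }

  NumericVector gbest(kmax);
  List cuts(kmax);
  for (int k = 1; k <= kmax; ++k) {
    gbest[k - 1] = F[(size_t)k * (m + 1) + m];
    std::vector<int> cc;
    int e = m;
    for (int kk = k; kk >= 2; --kk) {
      int s = bp[(size_t)kk * (m + 1) + e];
      cc.push_back(ends[s - 1]);
      e = s;
    }
    std::sort(cc.begin(), cc.end());
    cuts[k - 1] = IntegerVector(cc.begin(), cc.end());
  }
  return List::create(_["g"] = gbest, _["cuts"] = cuts, _["m"] = m);
}
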