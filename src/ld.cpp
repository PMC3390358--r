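#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// D' point estimate and likelihood-grid confidence interval from phased
// two-locus haplotype counts (Gabriel-style, flat prior, `tail` mass cut off
// from each end of the normalized likelihood over d' in [0, 1]).
static void dprime_ci_core(double n11, double n10, double n01, double n00,
                           double step, double tail,
                           double &dp, double &lo, double &hi) {
  double n = n11 + n10 + n01 + n00;
  double pA = (n11 + n10) / n, pB = (n11 + n01) / n;
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    dp = NA_REAL; lo = NA_REAL; hi = NA_REAL;
    return;
  }
  double D = n11 / n - pA * pB;
  if (D < 0) {  // orient so D >= 0
    std::swap(n11, n10); std::swap(n01, n00);
    pB = 1 - pB; D = -D;
  }
  double Dmax = std::min(pA * (1 - pB), (1 - pA) * pB);
  dp = D / Dmax;
  if (dp > 1) dp = 1;

  int npt = (int)std::floor(1.0 / step + 0.5) + 1;
  std::vector<double> ll(npt);
  double llmax = R_NegInf;
  for (int k = 0; k < npt; ++k) {
    double d = k * step;
    double p11 = pA * pB + d * Dmax;
    double p10 = pA * (1 - pB) - d * Dmax;
    double p01 = (1 - pA) * pB - d * Dmax;
    double p00 = (1 - pA) * (1 - pB) + d * Dmax;
    p11 = std::max(p11, 1e-12); p10 = std::max(p10, 1e-12);
    p01 = std::max(p01, 1e-12); p00 = std::max(p00, 1e-12);
    ll[k] = n11 * std::log(p11) + n10 * std::log(p10) +
            n01 * std::log(p01) + n00 * std::log(p00);
    if (ll[k] > llmax) llmax = ll[k];
  }
  double total = 0.0;
  std::vector<double> w(npt);
  for (int k = 0; k < npt; ++k) { w[k] = std::exp(ll[k] - llmax); total += w[k]; }
  double cum = 0.0;
  lo = 0.0; hi = 1.0;
  for (int k = 0; k < npt; ++k) {
    cum += w[k];
    if (cum >= tail * total) { lo = k * step; break; }
  }
  cum = 0.0;
  for (int k = npt - 1; k >= 0; --k) {
    cum += w[k];
    if (cum >= tail * total) { hi = k * step; break; }
  }
  if (hi < lo) hi = lo;
}

//' @noRd
// [[Rcpp::export(name = ".dprime_ci")]]
NumericVector dprime_ci_cpp(double n11, double n10, double n01, double n00,
                            double step = 0.005, double tail = 0.05) {
  double dp, lo, hi;
  dprime_ci_core(n11, n10, n01, n00, step, tail, dp, lo, hi);
  return NumericVector::create(_["dprime"] = dp, _["low"] = lo, _["high"] = hi);
}

// Gabriel-style haplotype blocks on phased data.
// Pair classes within max_span_bp: 1 = strong LD (CI low >= strong_lo and
// high >= strong_hi), 2 = strong evidence of recombination (CI high <
// recomb_hi), 0 = uninformative.  A candidate block [i, j] has a strong
// outermost pair and >= frac of its informative pairs strong; candidates are
// accepted greedily by decreasing genetic span.
//' @noRd
// [[Rcpp::export(name = ".gabriel_blocks")]]
List gabriel_blocks_cpp(IntegerMatrix H, NumericVector bp, NumericVector cm,
                        double maf_min = 0.05, double max_span_bp = 200000,
                        double strong_lo = 0.70, double strong_hi = 0.98,
                        double recomb_hi = 0.90, double frac = 0.95,
                        double step = 0.005, double tail = 0.05) {
  int N = H.nrow(), M = H.ncol();
  int words = (N + 63) / 64;
  std::vector<uint64_t> bits((size_t)M * words, 0);
  std::vector<double> cnt1(M, 0);
  for (int j = 0; j < M; ++j)
    for (int i = 0; i < N; ++i)
      if (H(i, j)) {
        bits[(size_t)j * words + (i >> 6)] |= (uint64_t)1 << (i & 63);
        cnt1[j] += 1;
      }
  std::vector<bool> keep(M);
  for (int j = 0; j < M; ++j) {
    double f = cnt1[j] / N;
    keep[j] = std::min(f, 1 - f) >= maf_min;
  }

  // banded pair classification
  std::vector<int> maxj(M);
  std::vector<std::vector<signed char> > cls(M);
  for (int i = 0; i < M; ++i) {
    int j = i + 1;
    while (j < M && bp[j] - bp[i] <= max_span_bp) ++j;
    maxj[i] = j - 1;
    cls[i].assign(std::max(0, maxj[i] - i), 0);
    if (!keep[i]) continue;
    for (j = i + 1; j <= maxj[i]; ++j) {
      if (!keep[j]) continue;
      uint64_t *a = &bits[(size_t)i * words], *b = &bits[(size_t)j * words];
      double n11 = 0;
      for (int wgt = 0; wgt < words; ++wgt)
        n11 += __builtin_popcountll(a[wgt] & b[wgt]);
      double nA = cnt1[i], nB = cnt1[j];
      double n10 = nA - n11, n01 = nB - n11, n00 = N - nA - nB + n11;
      double dp, lo, hi;
      dprime_ci_core(n11, n10, n01, n00, step, tail, dp, lo, hi);
      if (!R_FINITE(dp)) continue;
      signed char c = 0;
      if (lo >= strong_lo && hi >= strong_hi) c = 1;
      else if (hi < recomb_hi) c = 2;
      cls[i][j - i - 1] = c;
    }
  }

  // candidate blocks: strong outermost pair + frac rule over informative pairs
  struct Cand { int i, j; double cmspan, bpspan; };
  std::vector<Cand> cands;
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j <= maxj[i]; ++j) {
      if (cls[i][j - i - 1] != 1) continue;
      long strong = 0, recomb = 0;
      for (int a = i; a < j; ++a)
        for (int b2 = a + 1; b2 <= j && b2 <= maxj[a]; ++b2) {
          signed char c = cls[a][b2 - a - 1];
          if (c == 1) ++strong; else if (c == 2) ++recomb;
        }
      if (strong + recomb == 0) continue;
      if ((double)strong / (strong + recomb) >= frac)
        cands.push_back({i, j, cm[j] - cm[i], bp[j] - bp[i]});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand &x, const Cand &y) {
    if (x.cmspan != y.cmspan) return x.cmspan > y.cmspan;
    if (x.bpspan != y.bpspan) return x.bpspan > y.bpspan;
    return x.i < y.i;
  });
  std::vector<bool> used(M, false);
  std::vector<int> bi, bj;
  for (size_t c = 0; c < cands.size(); ++c) {
    bool free_ = true;
    for (int v = cands[c].i; v <= cands[c].j; ++v)
      if (used[v]) { free_ = false; break; }
    if (!free_) continue;
    for (int v = cands[c].i; v <= cands[c].j; ++v) used[v] = true;
    bi.push_back(cands[c].i + 1);  // 1-based for R
    bj.push_back(cands[c].j + 1);
  }
  return List::create(_["first"] = wrap(bi), _["last"] = wrap(bj));
}
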