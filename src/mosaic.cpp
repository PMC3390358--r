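#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Li-Stephens style mosaic resampling.  Each output haplotype copies a
// uniformly chosen template from the panel; template switches occur as a
// Poisson process along the genetic map with intensity lambda per cM (so the
// probability of switching between adjacent variants d cM apart is
// 1 - exp(-lambda * d), and the template after one or more switches is
// uniform on the panel); each copied allele flips with probability eps.
// Switch and flip events are generated by exponential/geometric skipping, so
// the per-site work is a plain copy.
//' @noRd
// [[Rcpp::export(name = ".mosaic_resample")]]
IntegerMatrix mosaic_resample(IntegerMatrix H, NumericVector gpos_cm,
                              int n_out, double lambda, double eps) {
  int k = H.nrow(), m = H.ncol();
  if (k < 1) stop("empty panel");
  if (m != gpos_cm.size()) stop("positions do not match panel columns");
  for (int s = 0; s + 1 < m; ++s)
    if (gpos_cm[s + 1] < gpos_cm[s])
      stop("genetic positions must be non-decreasing");

  RNGScope rng;
  IntegerMatrix out(n_out, m);
  double log1meps = (eps > 0) ? std::log(1.0 - eps) : 0.0;
  for (int i = 0; i < n_out; ++i) {
    int j = (int)(unif_rand() * k); if (j == k) j = k - 1;
    double next_switch = (lambda > 0 && m > 0)
      ? gpos_cm[0] + exp_rand() / lambda : R_PosInf;
    R_xlen_t next_flip = (eps > 0)
      ? (R_xlen_t)std::floor(std::log(unif_rand()) / log1meps) : -1;
    for (int s = 0; s < m; ++s) {
      while (gpos_cm[s] > next_switch) {
        j = (int)(unif_rand() * k); if (j == k) j = k - 1;
        next_switch += exp_rand() / lambda;
      }
      int a = H(j, s);
      if (eps > 0 && s == next_flip) {
        a = 1 - a;
        next_flip += 1 + (R_xlen_t)std::floor(std::log(unif_rand()) / log1meps);
      }
      out(i, s) = a;
    }
  }
  return out;
}
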