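#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Newton/IRLS fit of logit P(case) = b0 + b1 * g from a 2 x 3 table of
// phenotype x dosage counts (sufficient statistics for a {0,1,2}-coded
// marker).  Returns false on separation / non-convergence.
static bool fit_from_counts(const double ncell[2][3], double b0_init,
                            int maxit, double tol,
                            double &b1, double &se1) {
  double n_g[3], r_g[3];
  for (int g = 0; g < 3; ++g) {
    n_g[g] = ncell[0][g] + ncell[1][g];
    r_g[g] = ncell[1][g];
  }
  double b0 = b0_init; b1 = 0.0;
  double I00 = 0, I01 = 0, I11 = 0, det = 0;
  bool ok = false;
  for (int it = 0; it < maxit; ++it) {
    double U0 = 0, U1 = 0;
    I00 = I01 = I11 = 0;
    for (int g = 0; g < 3; ++g) {
      if (n_g[g] <= 0) continue;
      double eta = b0 + b1 * g;
      double p = 1.0 / (1.0 + std::exp(-eta));
      double w = n_g[g] * p * (1.0 - p);
      double r = r_g[g] - n_g[g] * p;
      U0 += r; U1 += g * r;
      I00 += w; I01 += g * w; I11 += g * g * w;
    }
    det = I00 * I11 - I01 * I01;
    if (det <= 1e-12 || !R_FINITE(det)) return false;
    double d0 = (I11 * U0 - I01 * U1) / det;
    double d1 = (I00 * U1 - I01 * U0) / det;
    b0 += d0; b1 += d1;
    if (std::fabs(b0) > 30 || std::fabs(b1) > 30) return false;
    if (std::fabs(d0) + std::fabs(d1) < tol) { ok = true; break; }
  }
  if (!ok) return false;
  se1 = std::sqrt(I00 / det);
  return R_FINITE(se1) && se1 <= 50 && std::fabs(b1) <= 12;
}

// General per-observation Newton fit for non-{0,1,2} dosage codings.
static bool fit_general(const NumericMatrix &G, int j,
                        const IntegerVector &y, double b0_init,
                        int maxit, double tol, double &b1, double &se1) {
  int n = G.nrow();
  double b0 = b0_init; b1 = 0.0;
  double I00 = 0, I01 = 0, I11 = 0, det = 0;
  bool ok = false;
  for (int it = 0; it < maxit; ++it) {
    double U0 = 0, U1 = 0;
    I00 = I01 = I11 = 0;
    for (int i = 0; i < n; ++i) {
      double g = G(i, j);
      double eta = b0 + b1 * g;
      double p = 1.0 / (1.0 + std::exp(-eta));
      double w = p * (1.0 - p);
      double r = y[i] - p;
      U0 += r; U1 += r * g;
      I00 += w; I01 += w * g; I11 += w * g * g;
    }
    det = I00 * I11 - I01 * I01;
    if (det <= 1e-12 || !R_FINITE(det)) return false;
    double d0 = (I11 * U0 - I01 * U1) / det;
    double d1 = (I00 * U1 - I01 * U0) / det;
    b0 += d0; b1 += d1;
    if (std::fabs(b0) > 30 || std::fabs(b1) > 30) return false;
    if (std::fabs(d0) + std::fabs(d1) < tol) { ok = true; break; }
  }
  if (!ok) return false;
  se1 = std::sqrt(I00 / det);
  return R_FINITE(se1) && se1 <= 50 && std::fabs(b1) <= 12;
}

// Per-marker logistic regression scan; Wald statistics for the dosage
// effect.  Flags: 0 = ok, 1 = monomorphic, 2 = unstable (separation or
// non-convergence; caller applies a Firth refit).  Returns M x 3:
// beta1, se1, flag.
//' @noRd
// [[Rcpp::export(name = ".logistic_scan")]]
NumericMatrix logistic_scan(NumericMatrix G, IntegerVector y,
                            int maxit = 30, double tol = 1e-8) {
  int n = G.nrow(), M = G.ncol();
  if (y.size() != n) stop("phenotype length does not match genotype rows");
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar <= 0 || ybar >= 1) stop("phenotype must contain both classes");
  double b0_init = std::log(ybar / (1.0 - ybar));

  NumericMatrix res(M, 3);
  for (int j = 0; j < M; ++j) {
    double ncell[2][3] = {{0, 0, 0}, {0, 0, 0}};
    bool tabular = true;
    for (int i = 0; i < n; ++i) {
      double g = G(i, j);
      int gi = (int)g;
      if (g != gi || gi < 0 || gi > 2) { tabular = false; break; }
      ncell[y[i]][gi] += 1;
    }
    bool mono;
    if (tabular) {
      int nonzero = 0;
      for (int g = 0; g < 3; ++g)
        if (ncell[0][g] + ncell[1][g] > 0) ++nonzero;
      mono = nonzero <= 1;
    } else {
      double g0 = G(0, j);
      mono = true;
      for (int i = 1; i < n; ++i) if (G(i, j) != g0) { mono = false; break; }
    }
    if (mono) {
      res(j, 0) = NA_REAL; res(j, 1) = NA_REAL; res(j, 2) = 1;
      continue;
    }
    double b1 = NA_REAL, se1 = NA_REAL;
    bool ok = tabular
      ? fit_from_counts(ncell, b0_init, maxit, tol, b1, se1)
      : fit_general(G, j, y, b0_init, maxit, tol, b1, se1);
    res(j, 0) = b1; res(j, 1) = se1; res(j, 2) = ok ? 0 : 2;
  }
  return res;
}

// Collapse a phased haplotype matrix (consecutive row pairs = individuals)
// to a dosage matrix.
//' @noRd
// [[Rcpp::export(name = ".hap_dosage")]]
IntegerMatrix hap_dosage(IntegerMatrix H) {
  int n2 = H.nrow(), m = H.ncol();
  if (n2 % 2) stop("haplotype count must be even");
  int n = n2 / 2;
  IntegerMatrix G(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      G(i, j) = H(2 * i, j) + H(2 * i + 1, j);
  return G;
}
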