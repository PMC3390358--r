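#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sequentially Markov coalescent (SMC') with piecewise-exponential demography.
//
// Backward-time demography segments: on [start[i], start[i+1]) the diploid
// size is N(t) = N0[i] * exp(-alpha[i] * (t - start[i])).  alpha > 0 means the
// population was growing forward in time (shrinking backward).  The last
// segment must be constant (alpha == 0) so waiting times are always finite.
struct Demography {
  std::vector<double> start, N0, alpha;

  int seg_of(double t) const {
    int i = (int)start.size() - 1;
    while (i > 0 && t < start[i]) --i;
    return i;
  }
  double seg_end(int i) const {
    return (i + 1 < (int)start.size()) ? start[i + 1] : R_PosInf;
  }
  // integral of 1/(2N(u)) du over [a, b], both inside segment i
  double cumhaz_seg(int i, double a, double b) const {
    if (alpha[i] == 0.0) return (b - a) / (2.0 * N0[i]);
    double ea = std::exp(alpha[i] * (a - start[i]));
    double eb = std::exp(alpha[i] * (b - start[i]));
    return (eb - ea) / (2.0 * N0[i] * alpha[i]);
  }
  // smallest b >= a with cumhaz_seg(i, a, b) == target
  double solve_seg(int i, double a, double target) const {
    if (alpha[i] == 0.0) return a + target * 2.0 * N0[i];
    double ea = std::exp(alpha[i] * (a - start[i]));
    return start[i] + std::log(ea + target * 2.0 * N0[i] * alpha[i]) / alpha[i];
  }
};

// Waiting time to an event starting at t0 when the hazard is
// pairs / (2 N(t)) with a constant combinatorial factor `pairs`.
static double draw_event_time(const Demography &dem, double t0, double pairs) {
  double E = exp_rand();
  double t = t0;
  int i = dem.seg_of(t0);
  for (;;) {
    double end = dem.seg_end(i);
    if (!R_FINITE(end)) return dem.solve_seg(i, t, E / pairs);
    double avail = pairs * dem.cumhaz_seg(i, t, end);
    if (E <= avail) return dem.solve_seg(i, t, E / pairs);
    E -= avail;
    t = end;
    ++i;
  }
}

struct Tree {
  int n;                       // leaves
  std::vector<int> parent, ch1, ch2;
  std::vector<double> time;
  int root;

  Tree(int n_) : n(n_), parent(2 * n_ - 1, -1), ch1(2 * n_ - 1, -1),
                 ch2(2 * n_ - 1, -1), time(2 * n_ - 1, 0.0), root(-1) {}

  double total_length() const {
    double L = 0.0;
    for (int v = 0; v < 2 * n - 1; ++v)
      if (v != root) L += time[parent[v]] - time[v];
    return L;
  }
  // edge chosen with probability proportional to its length; also returns a
  // uniform height on that edge via `u`
  int pick_edge(double L, double &u) const {
    double r = unif_rand() * L, acc = 0.0;
    int last = -1;
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (v == root) continue;
      double len = time[parent[v]] - time[v];
      acc += len;
      last = v;
      if (r <= acc) {
        u = time[parent[v]] - (acc - r);
        return v;
      }
    }
    u = time[parent[last]];
    return last;  // numerical guard
  }
  void leaves_under(int v, std::vector<int> &out) const {
    if (v < n) { out.push_back(v); return; }
    leaves_under(ch1[v], out);
    leaves_under(ch2[v], out);
  }
  void replace_child(int p, int oldc, int newc) {
    if (ch1[p] == oldc) ch1[p] = newc; else ch2[p] = newc;
  }
};

static void sample_initial_tree(Tree &tr, const Demography &dem) {
  int n = tr.n;
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next = n;
  for (int k = n; k >= 2; --k) {
    t = draw_event_time(dem, t, 0.5 * k * (k - 1));
    int ia = (int)(unif_rand() * k); if (ia == k) ia = k - 1;
    int ib = (int)(unif_rand() * (k - 1)); if (ib == k - 1) ib = k - 2;
    if (ib >= ia) ++ib;
    int a = active[ia], b = active[ib];
    tr.ch1[next] = a; tr.ch2[next] = b;
    tr.parent[a] = next; tr.parent[b] = next;
    tr.time[next] = t;
    active[std::min(ia, ib)] = next;
    active[std::max(ia, ib)] = active[k - 1];
    active.pop_back();
    ++next;
  }
  tr.root = next - 1;
  tr.parent[tr.root] = -1;
}

// One SMC' step: cut the tree at a uniform point, re-coalesce the floating
// lineage against the edges of the *original* tree (so re-coalescing onto the
// residual of the cut edge restores the tree, which is what distinguishes
// SMC' from SMC).
static void smc_prime_step(Tree &tr, const Demography &dem, double L) {
  int n = tr.n;
  double u;
  int b = tr.pick_edge(L, u);

  // internal node times, sorted: lineage count at t is n - #{times <= t}
  std::vector<double> itimes;
  itimes.reserve(n - 1);
  for (int v = n; v < 2 * n - 1; ++v) itimes.push_back(tr.time[v]);
  std::sort(itimes.begin(), itimes.end());

  // sample re-coalescence time tc, hazard k(t) / (2 N(t))
  double E = exp_rand();
  double t = u, tc = R_PosInf;
  size_t ci = std::upper_bound(itimes.begin(), itimes.end(), t) - itimes.begin();
  for (;;) {
    int k = n - (int)ci;
    if (k < 1) k = 1;
    double tnext = (ci < itimes.size()) ? itimes[ci] : R_PosInf;
    // integrate within [t, tnext), possibly across demography segments
    int i = dem.seg_of(t);
    bool done = false;
    double a = t;
    for (;;) {
      double end = std::min(dem.seg_end(i), tnext);
      double avail = R_FINITE(end) ? k * dem.cumhaz_seg(i, a, end) : R_PosInf;
      if (!R_FINITE(end)) { tc = dem.solve_seg(i, a, E / k); done = true; break; }
      if (E <= avail) { tc = dem.solve_seg(i, a, E / k); done = true; break; }
      E -= avail;
      a = end;
      if (end >= tnext) break;
      ++i;
    }
    if (done) break;
    t = tnext;
    ++ci;
  }

  // pick the target edge spanning tc, uniformly
  int target = -1;
  if (tc >= tr.time[tr.root]) {
    target = tr.root;
  } else {
    int cnt = 0;
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (v == tr.root) continue;
      if (tr.time[v] <= tc && tc < tr.time[tr.parent[v]]) ++cnt;
    }
    int pick = (int)(unif_rand() * cnt); if (pick == cnt) pick = cnt - 1;
    for (int v = 0; v < 2 * n - 1; ++v) {
      if (v == tr.root) continue;
      if (tr.time[v] <= tc && tc < tr.time[tr.parent[v]]) {
        if (pick-- == 0) { target = v; break; }
      }
    }
  }

  if (target == b) return;  // re-coalesced onto the residual: tree unchanged

  int p = tr.parent[b];
  int s = (tr.ch1[p] == b) ? tr.ch2[p] : tr.ch1[p];
  int g = tr.parent[p];
  if (target == p) target = s;  // p's parent edge merges into s's after splice

  // splice p out
  if (g == -1) { tr.root = s; tr.parent[s] = -1; }
  else { tr.replace_child(g, p, s); tr.parent[s] = g; }

  // re-attach p as the junction above `target` at height tc
  int pe = tr.parent[target];
  tr.parent[p] = pe;
  if (pe == -1) tr.root = p; else tr.replace_child(pe, target, p);
  tr.ch1[p] = b; tr.ch2[p] = target;
  tr.parent[b] = p; tr.parent[target] = p;
  tr.time[p] = tc;
}

//' @noRd
// [[Rcpp::export(name = ".smc_simulate")]]
List smc_simulate(int n_hap, double phys_len, double morgans_per_bp,
                  double mu, NumericVector dem_start, NumericVector dem_N0,
                  NumericVector dem_alpha) {
  if (n_hap < 2) stop("need at least 2 haplotypes");
  Demography dem;
  dem.start = as<std::vector<double> >(dem_start);
  dem.N0 = as<std::vector<double> >(dem_N0);
  dem.alpha = as<std::vector<double> >(dem_alpha);
  if (dem.alpha.back() != 0.0) stop("terminal demography segment must be constant");

  RNGScope rng;
  Tree tr(n_hap);
  sample_initial_tree(tr, dem);

  double G = phys_len * morgans_per_bp;  // genetic length in Morgans
  std::vector<double> mut_pos;
  std::vector<std::vector<int> > mut_leaves;

  double g = 0.0;
  for (;;) {
    double L = tr.total_length();
    double step = (L > 0) ? exp_rand() / L : R_PosInf;
    double gnext = std::min(g + step, G);
    // mutations on [g, gnext)
    double p1 = g / morgans_per_bp, p2 = gnext / morgans_per_bp;
    if (mu > 0 && p2 > p1) {
      int nmut = (int)R::rpois(mu * (p2 - p1) * L);
      for (int m = 0; m < nmut; ++m) {
        double uu;
        int v = tr.pick_edge(L, uu);
        std::vector<int> lv;
        tr.leaves_under(v, lv);
        if ((int)lv.size() == n_hap) continue;  // fixed: not polymorphic
        mut_pos.push_back(p1 + unif_rand() * (p2 - p1));
        mut_leaves.push_back(lv);
      }
    }
    if (gnext >= G) break;
    smc_prime_step(tr, dem, L);
    g = gnext;
  }

  // order by position, resolve bp collisions
  int S = (int)mut_pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });
  IntegerMatrix H(n_hap, S);
  NumericVector pos(S);
  double prev = -1.0;
  for (int j = 0; j < S; ++j) {
    int i = ord[j];
    double bp = std::floor(mut_pos[i]) + 1.0;  // 1-based bp
    if (bp <= prev) bp = prev + 1.0;
    prev = bp;
    pos[j] = bp;
    const std::vector<int> &lv = mut_leaves[i];
    for (size_t q = 0; q < lv.size(); ++q) H(lv[q], j) = 1;
  }
  return List::create(_["haplotypes"] = H, _["position"] = pos);
}
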