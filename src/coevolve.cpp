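// Event-level core of the coevolutionary simulator.
//
// One elementary event per step: with probability W a pairwise-comparison
// imitation event, otherwise a rewiring event. Strategies are coded
// 1 = cooperator, 0 = defector; link types index k_probs as
// s_a + s_b (0 = DD, 1 = CD, 2 = CC). All randomness comes from R's
// generator (unif_rand/norm_rand under RNGScope), so runs are reproducible
// from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

inline int draw_int(int n) {
  // uniform on {0, ..., n-1}
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

inline double fermi_prob(double pi_i, double pi_j, double beta) {
  double z = beta * (pi_j - pi_i);
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

struct Population {
  int N, L;
  std::vector<int> strat;            // 1 = C, 0 = D
  std::vector<int> e1, e2;           // edge endpoints (0-based)
  std::vector<std::vector<int> > adj;
  long cnt[3];                       // link counts by type (s_a + s_b)
  int nC;

  void init(const IntegerVector& strat0, const IntegerMatrix& edges0) {
    N = strat0.size();
    L = edges0.nrow();
    strat.assign(strat0.begin(), strat0.end());
    e1.resize(L); e2.resize(L);
    adj.assign(N, std::vector<int>());
    cnt[0] = cnt[1] = cnt[2] = 0;
    nC = 0;
    for (int i = 0; i < N; ++i) nC += strat[i];
    for (int i = 0; i < L; ++i) {
      int a = edges0(i, 0), b = edges0(i, 1);
      e1[i] = a; e2[i] = b;
      adj[a].push_back(b);
      adj[b].push_back(a);
      ++cnt[strat[a] + strat[b]];
    }
  }

  bool is_neighbor(int u, int v) const {
    const std::vector<int>& a = adj[u];
    return std::find(a.begin(), a.end(), v) != a.end();
  }

  void remove_adj(int u, int v) {
    std::vector<int>& a = adj[u];
    std::vector<int>::iterator it = std::find(a.begin(), a.end(), v);
    *it = a.back();
    a.pop_back();
  }

  double payoff_of(int u, const double pay[2][2]) const {
    double s = 0.0;
    const std::vector<int>& a = adj[u];
    for (size_t i = 0; i < a.size(); ++i) s += pay[strat[u]][strat[a[i]]];
    return s;
  }

  // full structural audit (test mode): simplicity, degree sum, counts
  void audit() const {
    std::vector<long long> seen;
    seen.reserve(L);
    long c[3] = {0, 0, 0};
    size_t degsum = 0;
    for (int i = 0; i < L; ++i) {
      if (e1[i] == e2[i]) stop("invariant violation: self-loop");
      int a = std::min(e1[i], e2[i]), b = std::max(e1[i], e2[i]);
      seen.push_back(static_cast<long long>(a) * N + b);
      ++c[strat[a] + strat[b]];
    }
    std::sort(seen.begin(), seen.end());
    for (int i = 1; i < L; ++i)
      if (seen[i] == seen[i - 1]) stop("invariant violation: duplicate edge");
    for (int u = 0; u < N; ++u) degsum += adj[u].size();
    if (static_cast<long>(degsum) != 2L * L)
      stop("invariant violation: degree sum != 2L");
    for (int t = 0; t < 3; ++t)
      if (c[t] != cnt[t]) stop("invariant violation: link-type counts drifted");
  }
};

} // namespace

// [[Rcpp::export]]
List run_core(IntegerVector strat0, IntegerMatrix edges0, NumericMatrix pay_cd,
              NumericVector kprobs, double W, double beta,
              int generations, bool check, bool early_exit) {
  Population pop;
  pop.init(strat0, edges0);
  const int N = pop.N, L = pop.L;
  // pay[s_focal][s_partner], strategy code 1 = C, 0 = D;
  // pay_cd arrives in (C, D) order
  double pay[2][2];
  pay[1][1] = pay_cd(0, 0);  // R
  pay[1][0] = pay_cd(0, 1);  // S
  pay[0][1] = pay_cd(1, 0);  // T
  pay[0][0] = pay_cd(1, 1);  // P
  // k by type index s_a + s_b: 0 = DD, 1 = CD, 2 = CC
  double k[3];
  k[2] = kprobs[0]; k[1] = kprobs[1]; k[0] = kprobs[2];

  NumericVector x_t(generations), f_cc(generations), f_cd(generations),
      f_dd(generations);
  long breaks = 0, cancelled = 0, flips = 0, isolated_focal = 0,
       strategy_events = 0, linking_events = 0;
  int absorbed_gen = NA_INTEGER;

  for (int gen = 0; gen < generations; ++gen) {
    for (int stepi = 0; stepi < N; ++stepi) {
      if (unif_rand() < W) {
        // ---- imitation event ----
        ++strategy_events;
        int f = draw_int(N);
        int deg = static_cast<int>(pop.adj[f].size());
        if (deg == 0) { ++isolated_focal; continue; }
        int j = pop.adj[f][draw_int(deg)];
        if (pop.strat[j] != pop.strat[f]) {
          double pf = pop.payoff_of(f, pay);
          double pj = pop.payoff_of(j, pay);
          if (unif_rand() < fermi_prob(pf, pj, beta)) {
            int olds = pop.strat[f], news = pop.strat[j];
            const std::vector<int>& a = pop.adj[f];
            for (size_t q = 0; q < a.size(); ++q) {
              --pop.cnt[olds + pop.strat[a[q]]];
              ++pop.cnt[news + pop.strat[a[q]]];
            }
            pop.strat[f] = news;
            pop.nC += news - olds;
            ++flips;
          }
        }
      } else {
        // ---- rewiring event ----
        ++linking_events;
        if (L == 0) continue;
        int ei = draw_int(L);
        int a = pop.e1[ei], b = pop.e2[ei];
        int type = pop.strat[a] + pop.strat[b];
        if (unif_rand() < k[type]) {
          int keeper = (unif_rand() < 0.5) ? a : b;
          if (static_cast<int>(pop.adj[keeper].size()) >= N - 1) {
            ++cancelled;  // linked to everyone: break cancelled, edge kept
          } else {
            int np;
            do {
              np = draw_int(N);
            } while (np == keeper || pop.is_neighbor(keeper, np));
            ++breaks;
            int other = (keeper == a) ? b : a;
            --pop.cnt[type];
            ++pop.cnt[pop.strat[keeper] + pop.strat[np]];
            pop.remove_adj(keeper, other);
            pop.remove_adj(other, keeper);
            pop.adj[keeper].push_back(np);
            pop.adj[np].push_back(keeper);
            pop.e1[ei] = keeper; pop.e2[ei] = np;
            if (check) {
              if (np == keeper) stop("invariant violation: self-loop created");
              int seen = 0;
              const std::vector<int>& ak = pop.adj[keeper];
              for (size_t q = 0; q < ak.size(); ++q) seen += (ak[q] == np);
              if (seen != 1) stop("invariant violation: duplicate edge created");
            }
          }
        }
      }
    }
    x_t[gen] = static_cast<double>(pop.nC) / N;
    f_cc[gen] = L > 0 ? static_cast<double>(pop.cnt[2]) / L : 0.0;
    f_cd[gen] = L > 0 ? static_cast<double>(pop.cnt[1]) / L : 0.0;
    f_dd[gen] = L > 0 ? static_cast<double>(pop.cnt[0]) / L : 0.0;
    if (check) pop.audit();
    if (early_exit && W > 0 && (pop.nC == 0 || pop.nC == N)) {
      // absorbing state (no mutation): pad the remaining series exactly
      for (int g2 = gen + 1; g2 < generations; ++g2) {
        x_t[g2] = x_t[gen];
        f_cc[g2] = f_cc[gen]; f_cd[g2] = f_cd[gen]; f_dd[g2] = f_dd[gen];
      }
      absorbed_gen = gen + 1;  // 1-based for the R side
      break;
    }
  }

  IntegerMatrix edges_out(L, 2);
  for (int i = 0; i < L; ++i) {
    edges_out(i, 0) = std::min(pop.e1[i], pop.e2[i]);
    edges_out(i, 1) = std::max(pop.e1[i], pop.e2[i]);
  }
  return List::create(
      _["x"] = x_t, _["f_cc"] = f_cc, _["f_cd"] = f_cd, _["f_dd"] = f_dd,
      _["strategies"] = IntegerVector(pop.strat.begin(), pop.strat.end()),
      _["edges"] = edges_out,
      _["absorbed_gen"] = absorbed_gen,
      _["counters"] = List::create(
          _["breaks"] = static_cast<double>(breaks),
          _["cancelled_breaks"] = static_cast<double>(cancelled),
          _["flips"] = static_cast<double>(flips),
          _["isolated_focal"] = static_cast<double>(isolated_focal),
          _["strategy_events"] = static_cast<double>(strategy_events),
          _["linking_events"] = static_cast<double>(linking_events)));
}
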