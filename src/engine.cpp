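// Core Dirichlet-multinomial partition engine.
//
// The count matrix arrives in compressed sparse column layout with cells as
// columns (slots of a dgCMatrix transposed to cells-in-columns by the R
// wrapper).  Cluster statistics are dense per-cluster gene-count arrays so a
// single-cell move touches only the moved cell's nonzero genes plus two
// total-count terms.  All log-likelihoods omit the per-cell multinomial
// coefficients, which are identical for every partition.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

class Engine {
public:
  int G, C;
  const int *ci;    // gene index per nonzero entry (0-based)
  const int *cp;    // column pointers, length C+1
  const double *cx; // counts (integral values)
  std::vector<double> thg; // theta_g
  double thsum;

  std::vector<double> Nc; // per-cell totals

  // cluster state: ids are slots in these arrays, some inactive
  std::vector<std::vector<int> > cc; // per-cluster dense gene counts
  std::vector<double> Ns;
  std::vector<int> sz;
  std::vector<int> assign;   // cell -> cluster id
  std::vector<int> active;   // active cluster ids
  std::vector<int> pos;      // cluster id -> index in active (-1 if inactive)
  std::vector<int> freelist;

  // lazily filled lgamma(theta_g + n) cache, one vector per gene
  std::vector<std::vector<double> > lgc;

  Engine(const IntegerVector &ci_, const IntegerVector &cp_,
         const NumericVector &cx_, int G_,
         const NumericVector &theta_g, double theta_sum,
         const IntegerVector &assign0)
      : G(G_), C(cp_.size() - 1), ci(ci_.begin()), cp(cp_.begin()),
        cx(cx_.begin()), thg(theta_g.begin(), theta_g.end()),
        thsum(theta_sum) {
    if ((int)thg.size() != G) stop("theta_g length does not match gene count");
    lgc.assign(G, std::vector<double>());
    Nc.assign(C, 0.0);
    for (int u = 0; u < C; ++u)
      for (int k = cp[u]; k < cp[u + 1]; ++k) Nc[u] += cx[k];

    int maxid = 0;
    for (int u = 0; u < C; ++u) maxid = std::max(maxid, assign0[u]);
    cc.assign(maxid, std::vector<int>());
    Ns.assign(maxid, 0.0);
    sz.assign(maxid, 0);
    pos.assign(maxid, -1);
    assign.resize(C);
    for (int u = 0; u < C; ++u) {
      int s = assign0[u] - 1; // to 0-based ids
      if (s < 0) stop("assignment labels must be positive integers");
      assign[u] = s;
      if (sz[s] == 0) {
        cc[s].assign(G, 0);
        pos[s] = (int)active.size();
        active.push_back(s);
      }
      sz[s] += 1;
      Ns[s] += Nc[u];
      for (int k = cp[u]; k < cp[u + 1]; ++k) cc[s][ci[k]] += (int)cx[k];
    }
    for (int s = 0; s < maxid; ++s)
      if (pos[s] == -1) freelist.push_back(s);
  }

  inline double lgt(int g, int n) {
    std::vector<double> &v = lgc[g];
    if ((int)v.size() <= n)
      v.resize(n + 1, std::numeric_limits<double>::quiet_NaN());
    double &r = v[n];
    if (std::isnan(r)) r = std::lgamma(thg[g] + n);
    return r;
  }

  int nclusters() const { return (int)active.size(); }

  // log marginal contribution of one cluster
  double cluster_term(int s) {
    double t = std::lgamma(thsum) - std::lgamma(thsum + Ns[s]);
    const std::vector<int> &v = cc[s];
    for (int g = 0; g < G; ++g)
      if (v[g] > 0) t += lgt(g, v[g]) - lgt(g, 0);
    return t;
  }

  double total_loglik() {
    double t = 0.0;
    for (size_t a = 0; a < active.size(); ++a) t += cluster_term(active[a]);
    return t;
  }

  // delta log-likelihood of moving cell u from its cluster to t (-1 = NEW)
  double delta(int u, int t) {
    int s = assign[u];
    double d = 0.0;
    const std::vector<int> *tv = (t >= 0) ? &cc[t] : 0;
    const std::vector<int> &sv = cc[s];
    for (int k = cp[u]; k < cp[u + 1]; ++k) {
      int g = ci[k], x = (int)cx[k];
      int nt = tv ? (*tv)[g] : 0;
      d += lgt(g, nt + x) - lgt(g, nt);
      int ns = sv[g];
      d += lgt(g, ns - x) - lgt(g, ns);
    }
    double Nt = (t >= 0) ? Ns[t] : 0.0;
    d += std::lgamma(thsum + Nt) - std::lgamma(thsum + Nt + Nc[u]);
    d += std::lgamma(thsum + Ns[s]) - std::lgamma(thsum + Ns[s] - Nc[u]);
    return d;
  }

  void deactivate(int s) {
    int p = pos[s];
    int last = active.back();
    active[p] = last;
    pos[last] = p;
    active.pop_back();
    pos[s] = -1;
    freelist.push_back(s);
  }

  int activate_new() {
    int s;
    if (!freelist.empty()) {
      s = freelist.back();
      freelist.pop_back();
    } else {
      s = (int)cc.size();
      cc.push_back(std::vector<int>());
      Ns.push_back(0.0);
      sz.push_back(0);
      pos.push_back(-1);
    }
    cc[s].assign(G, 0);
    Ns[s] = 0.0;
    sz[s] = 0;
    pos[s] = (int)active.size();
    active.push_back(s);
    return s;
  }

  // apply the move; returns the target cluster id actually used
  int apply_move(int u, int t) {
    int s = assign[u];
    if (t < 0) t = activate_new();
    for (int k = cp[u]; k < cp[u + 1]; ++k) {
      int g = ci[k], x = (int)cx[k];
      cc[s][g] -= x;
      cc[t][g] += x;
    }
    Ns[s] -= Nc[u];
    Ns[t] += Nc[u];
    sz[s] -= 1;
    sz[t] += 1;
    assign[u] = t;
    if (sz[s] == 0) deactivate(s);
    return t;
  }

  // merge log-likelihood ratio for two distinct active clusters
  double merge_ratio(int a, int b) {
    double d = 0.0;
    const std::vector<int> &va = cc[a], &vb = cc[b];
    for (int g = 0; g < G; ++g) {
      int na = va[g], nb = vb[g];
      if (na == 0 && nb == 0) continue;
      d += lgt(g, na + nb) - lgt(g, na) - lgt(g, nb) + lgt(g, 0);
    }
    d += std::lgamma(thsum + Ns[a]) + std::lgamma(thsum + Ns[b]) -
         std::lgamma(thsum) - std::lgamma(thsum + Ns[a] + Ns[b]);
    return d;
  }

  void merge_into(int a, int b) { // all of b's cells join a
    for (int u = 0; u < C; ++u)
      if (assign[u] == b) assign[u] = a;
    const std::vector<int> &vb = cc[b];
    for (int g = 0; g < G; ++g) cc[a][g] += vb[g];
    Ns[a] += Ns[b];
    sz[a] += sz[b];
    sz[b] = 0;
    Ns[b] = 0.0;
    deactivate(b);
  }

  IntegerVector assignment_1based() const {
    IntegerVector out(C);
    for (int u = 0; u < C; ++u) out[u] = assign[u] + 1;
    return out;
  }
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

} // namespace

// [[Rcpp::export]]
List cpp_mcmc(IntegerVector ci, IntegerVector cp, NumericVector cx, int G,
              NumericVector theta_g, double theta_sum, IntegerVector assign0,
              int n_sweeps, int conv_window, int stall0, bool allow_new,
              bool uphill_only) {
  Engine e(ci, cp, cx, G, theta_g, theta_sum, assign0);
  RNGScope rng;
  double ll = e.total_loglik();
  // fp-noise floor for "strict" improvements: lgamma terms have magnitude
  // up to lgamma(theta_sum + N), whose rounding error scales with the
  // argument, so a fixed epsilon would misclassify noise as progress
  double grand_total = 0.0;
  for (int u = 0; u < e.C; ++u) grand_total += e.Nc[u];
  const double eps = 1e-10 * (theta_sum + grand_total) + 1e-10;
  int stall = stall0;
  long n_prop = 0, n_acc = 0, n_acc_up = 0;
  int sweeps_done = 0;
  bool converged = (stall >= conv_window);
  std::vector<double> trace;
  trace.reserve(n_sweeps);

  for (int sweep = 0; sweep < n_sweeps && !converged; ++sweep) {
    for (int it = 0; it < e.C && !converged; ++it) {
      int u = runif_int(e.C);
      int s = e.assign[u];
      int K = e.nclusters();
      bool singleton = (e.sz[s] == 1);
      int T = (K - 1) + ((allow_new && !singleton) ? 1 : 0);
      ++n_prop;
      ++stall;
      if (T <= 0) { // single cluster of identical cells, nothing to propose
        if (stall >= conv_window) converged = true;
        continue;
      }
      int j = runif_int(T);
      int t; // target id, -1 for NEW
      if (j >= K - 1) {
        t = -1;
      } else {
        // j-th active cluster skipping the current one
        int idx = (j >= e.pos[s]) ? j + 1 : j;
        t = e.active[idx];
      }
      double d = e.delta(u, t);
      if (!std::isfinite(d))
        stop("non-finite likelihood delta at cell %d", u + 1);
      bool accept;
      if (d > 0) {
        accept = true;
      } else if (uphill_only) {
        accept = false;
      } else {
        // Metropolis-Hastings correction for the changing target-set size
        int Kafter, Tafter;
        if (t == -1) { // cell becomes a singleton in a new cluster
          Kafter = K + 1;
          Tafter = Kafter - 1;
        } else if (singleton) { // source disappears
          Kafter = K - 1;
          Tafter = (Kafter - 1) + (allow_new ? 1 : 0);
        } else {
          Kafter = K;
          Tafter = (Kafter - 1) + (allow_new ? 1 : 0);
        }
        double p = std::exp(d) * ((double)T / (double)Tafter);
        accept = (unif_rand() < p);
      }
      if (accept) {
        e.apply_move(u, t);
        ll += d;
        ++n_acc;
        // improvements below fp noise must not reset the stall counter,
        // or a likelihood that is flat in the partition never converges
        if (d > eps) {
          ++n_acc_up;
          stall = 0;
        }
      }
      if (stall >= conv_window) converged = true;
    }
    ++sweeps_done;
    trace.push_back(ll);
  }

  return List::create(
      _["assignment"] = e.assignment_1based(), _["loglik"] = e.total_loglik(),
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["stall"] = stall, _["sweeps_done"] = sweeps_done,
      _["converged"] = converged, _["n_proposed"] = (double)n_prop,
      _["n_accepted"] = (double)n_acc, _["n_accepted_uphill"] = (double)n_acc_up);
}

// [[Rcpp::export]]
List cpp_refine(IntegerVector ci, IntegerVector cp, NumericVector cx, int G,
                NumericVector theta_g, double theta_sum,
                IntegerVector assign0) {
  Engine e(ci, cp, cx, G, theta_g, theta_sum, assign0);
  long n_moves = 0, n_merges = 0;
  double grand_total = 0.0;
  for (int u = 0; u < e.C; ++u) grand_total += e.Nc[u];
  // strict-improvement guard scaled to the magnitude of the lgamma terms
  const double eps = 1e-10 * (theta_sum + grand_total) + 1e-10;
  bool changed = true;
  while (changed) {
    changed = false;
    // (a) best single-cell moves, cells in index order, targets by ascending
    // internal cluster id (ties resolved to the lowest id by strict >)
    for (int u = 0; u < e.C; ++u) {
      int s = e.assign[u];
      std::vector<int> targets(e.active);
      std::sort(targets.begin(), targets.end());
      double best = eps;
      int best_t = -2;
      for (size_t a = 0; a < targets.size(); ++a) {
        int t = targets[a];
        if (t == s) continue;
        double d = e.delta(u, t);
        if (d > best) {
          best = d;
          best_t = t;
        }
      }
      if (e.sz[s] > 1) { // NEW-cluster split candidate
        double d = e.delta(u, -1);
        if (d > best) {
          best = d;
          best_t = -1;
        }
      }
      if (best_t != -2) {
        e.apply_move(u, best_t);
        ++n_moves;
        changed = true;
      }
    }
    // (b) pairwise merges in ascending id order
    bool merged = true;
    while (merged) {
      merged = false;
      std::vector<int> ids(e.active);
      std::sort(ids.begin(), ids.end());
      for (size_t a = 0; a < ids.size() && !merged; ++a) {
        if (e.pos[ids[a]] == -1) continue;
        for (size_t b = a + 1; b < ids.size() && !merged; ++b) {
          if (e.pos[ids[b]] == -1) continue;
          if (e.merge_ratio(ids[a], ids[b]) > eps) {
            e.merge_into(ids[a], ids[b]);
            ++n_merges;
            changed = true;
            merged = true;
          }
        }
      }
    }
  }
  return List::create(_["assignment"] = e.assignment_1based(),
                      _["loglik"] = e.total_loglik(),
                      _["n_moves"] = (double)n_moves,
                      _["n_merges"] = (double)n_merges);
}

// [[Rcpp::export]]
List cpp_loglik(IntegerVector ci, IntegerVector cp, NumericVector cx, int G,
                NumericVector theta_g, double theta_sum,
                IntegerVector assign0) {
  Engine e(ci, cp, cx, G, theta_g, theta_sum, assign0);
  std::vector<int> ids(e.active);
  std::sort(ids.begin(), ids.end());
  NumericVector per(ids.size());
  IntegerVector lab(ids.size());
  double tot = 0.0;
  for (size_t a = 0; a < ids.size(); ++a) {
    per[a] = e.cluster_term(ids[a]);
    lab[a] = ids[a] + 1;
    tot += per[a];
  }
  return List::create(_["total"] = tot, _["per_cluster"] = per,
                      _["cluster"] = lab);
}

// [[Rcpp::export]]
double cpp_delta_move(IntegerVector ci, IntegerVector cp, NumericVector cx,
                      int G, NumericVector theta_g, double theta_sum,
                      IntegerVector assign0, int cell, int target) {
  Engine e(ci, cp, cx, G, theta_g, theta_sum, assign0);
  return e.delta(cell - 1, target == 0 ? -1 : target - 1);
}
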