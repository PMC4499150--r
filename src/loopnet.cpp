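// Core learners: BDeu family scoring with memoisation, acyclicity-preserving
// edge operations, the grouped genetic algorithm and the structure MCMC.
// All randomness draws from R's RNG so results are reproducible from R seeds.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

typedef std::vector<unsigned char> Adj; // row-major n x n, a[u*n+v] = edge u->v

static inline int ri(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct Scorer {
  const int* x;        // data, genes x samples, column-major
  int n, ns, k;
  double ess;
  const double* logL;  // n x n column-major edge log-prior
  std::unordered_map<std::string, double> memo;

  double family(int node, const std::vector<int>& parents) {
    std::string key;
    key.reserve(2 * (parents.size() + 1));
    key.push_back((char)(node & 0xff));
    key.push_back((char)((node >> 8) & 0xff));
    for (int p : parents) {
      key.push_back((char)(p & 0xff));
      key.push_back((char)((p >> 8) & 0xff));
    }
    std::unordered_map<std::string, double>::iterator it = memo.find(key);
    if (it != memo.end()) return it->second;
    int np = (int)parents.size();
    long q = 1;
    for (int i = 0; i < np; i++) q *= k;
    std::vector<int> cnt((size_t)q * k, 0);
    for (int s = 0; s < ns; s++) {
      long cfg = 0, mult = 1;
      for (int i = 0; i < np; i++) {
        cfg += (long)(x[parents[i] + (size_t)n * s] - 1) * mult;
        mult *= k;
      }
      cnt[cfg * k + (x[node + (size_t)n * s] - 1)]++;
    }
    double aj = ess / q, ajk = ess / (q * (double)k);
    double val = 0.0;
    for (long j = 0; j < q; j++) {
      int Nj = 0;
      for (int c = 0; c < k; c++) Nj += cnt[j * k + c];
      if (Nj == 0) continue;  // unobserved configurations contribute zero
      val += std::lgamma(aj) - std::lgamma(aj + Nj);
      for (int c = 0; c < k; c++) {
        int N = cnt[j * k + c];
        if (N > 0) val += std::lgamma(ajk + N) - std::lgamma(ajk);
      }
    }
    memo[key] = val;
    return val;
  }

  double family_of(const Adj& adj, int v) {
    std::vector<int> par;
    for (int u = 0; u < n; u++) if (adj[(size_t)u * n + v]) par.push_back(u);
    return family(v, par);
  }

  double net_score(const Adj& adj) {
    double s = 0.0;
    for (int v = 0; v < n; v++) s += family_of(adj, v);
    for (int u = 0; u < n; u++)
      for (int v = 0; v < n; v++)
        if (adj[(size_t)u * n + v]) s += logL[u + (size_t)n * v];
    return s;
  }
};

static bool reachable(const Adj& adj, int n, int from, int to) {
  if (from == to) return true;
  std::vector<unsigned char> vis(n, 0);
  std::vector<int> stack;
  stack.push_back(from);
  vis[from] = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    const unsigned char* row = &adj[(size_t)u * n];
    for (int v = 0; v < n; v++) {
      if (row[v] && !vis[v]) {
        if (v == to) return true;
        vis[v] = 1;
        stack.push_back(v);
      }
    }
  }
  return false;
}

// add u->v if acyclic and within the parent cap; returns success
static bool try_add(Adj& adj, int n, int u, int v, int maxp,
                    std::vector<int>& indeg) {
  if (u == v || adj[(size_t)u * n + v]) return false;
  if (indeg[v] >= maxp) return false;
  if (reachable(adj, n, v, u)) return false;  // u reachable from v => cycle
  adj[(size_t)u * n + v] = 1;
  indeg[v]++;
  return true;
}

static std::vector<int> indegrees(const Adj& adj, int n) {
  std::vector<int> d(n, 0);
  for (int u = 0; u < n; u++)
    for (int v = 0; v < n; v++) d[v] += adj[(size_t)u * n + v];
  return d;
}

static Adj init_adj_cpp(int n, const std::vector<int>& pu,
                        const std::vector<int>& pv,
                        const std::vector<double>& pp,
                        double poisson_rate,
                        const std::vector<int>& sources, int maxp) {
  Adj adj((size_t)n * n, 0);
  std::vector<int> indeg(n, 0);
  int m = (int)pu.size();
  std::vector<int> ord;
  for (int i = 0; i < m; i++) if (unif_rand() < pp[i]) ord.push_back(i);
  // random insertion order, cycle-rejecting
  for (int i = (int)ord.size() - 1; i > 0; i--) std::swap(ord[i], ord[ri(i + 1)]);
  for (size_t i = 0; i < ord.size(); i++)
    try_add(adj, n, pu[ord[i]], pv[ord[i]], maxp, indeg);
  if (poisson_rate > 0 && !sources.empty()) {
    for (size_t si = 0; si < sources.size(); si++) {
      int d = (int)R::rpois(poisson_rate);
      for (int j = 0; j < d; j++)
        try_add(adj, n, sources[si], ri(n), maxp, indeg);
    }
  }
  return adj;
}

static Adj crossover(const Adj& a, const Adj& b, int n, int maxp) {
  std::vector<int> keep;
  for (size_t i = 0; i < a.size(); i++) {
    if (a[i] && b[i]) keep.push_back((int)i);
    else if (a[i] || b[i]) { if (unif_rand() < 0.5) keep.push_back((int)i); }
  }
  for (int i = (int)keep.size() - 1; i > 0; i--) std::swap(keep[i], keep[ri(i + 1)]);
  Adj adj((size_t)n * n, 0);
  std::vector<int> indeg(n, 0);
  for (size_t i = 0; i < keep.size(); i++)
    try_add(adj, n, keep[i] / n, keep[i] % n, maxp, indeg);
  return adj;
}

static void mutate(Adj& adj, int n, double rate, int maxp,
                   const std::vector<int>& sources) {
  if (rate <= 0) return;
  int m = (int)R::rpois(rate);
  if (m == 0) return;
  std::vector<int> indeg = indegrees(adj, n);
  for (int i = 0; i < m; i++) {
    int op = ri(3);
    if (op == 0) {  // add
      int u = sources.empty() ? ri(n) : sources[ri((int)sources.size())];
      try_add(adj, n, u, ri(n), maxp, indeg);
    } else {
      std::vector<int> edges;
      for (size_t e = 0; e < adj.size(); e++) if (adj[e]) edges.push_back((int)e);
      if (edges.empty()) continue;
      int e = edges[ri((int)edges.size())];
      int u = e / n, v = e % n;
      adj[e] = 0;
      indeg[v]--;
      if (op == 2) {  // reverse; restore on failure
        if (!try_add(adj, n, v, u, maxp, indeg)) {
          adj[e] = 1;
          indeg[v]++;
        }
      }
    }
  }
}

static Adj as_adj(const LogicalMatrix& m) {
  int n = m.nrow();
  Adj adj((size_t)n * n, 0);
  for (int u = 0; u < n; u++)
    for (int v = 0; v < n; v++) if (m(u, v)) adj[(size_t)u * n + v] = 1;
  return adj;
}

static LogicalMatrix as_matrix(const Adj& adj, int n) {
  LogicalMatrix m(n, n);
  for (int u = 0; u < n; u++)
    for (int v = 0; v < n; v++) m(u, v) = adj[(size_t)u * n + v] != 0;
  return m;
}

// [[Rcpp::export]]
List cpp_evolve(IntegerMatrix data, int k, List pop0,
                IntegerVector pri_u, IntegerVector pri_v, NumericVector pri_p,
                NumericMatrix logL, double ess, int max_parents,
                int max_gen, NumericVector mut_rates, double poisson_rate,
                int plateau_window, double plateau_tol,
                IntegerVector mut_sources, IntegerVector init_sources,
                bool crossover_enabled) {
  int n = data.nrow();
  Scorer sc;
  sc.x = INTEGER(data);
  sc.n = n;
  sc.ns = data.ncol();
  sc.k = k;
  sc.ess = ess;
  sc.logL = REAL(logL);

  std::vector<int> pu(pri_u.begin(), pri_u.end());
  std::vector<int> pv(pri_v.begin(), pri_v.end());
  std::vector<double> pp(pri_p.begin(), pri_p.end());
  std::vector<int> msrc(mut_sources.begin(), mut_sources.end());
  std::vector<int> isrc(init_sources.begin(), init_sources.end());

  int P = pop0.size();
  std::vector<Adj> pop(P);
  for (int i = 0; i < P; i++) pop[i] = as_adj(as<LogicalMatrix>(pop0[i]));
  std::vector<double> fit(P);
  for (int i = 0; i < P; i++) fit[i] = sc.net_score(pop[i]);

  // fitness-quartile group sizes (as equal as possible)
  int gs[4];
  int base = P / 4, rem = P % 4;
  for (int g = 0; g < 4; g++) gs[g] = base + (g < rem ? 1 : 0);

  std::vector<double> tr_gen, tr_fit, tr_prior, tr_edges;
  std::vector<double> best_hist;
  Adj prior_mask((size_t)n * n, 0);
  for (size_t i = 0; i < pu.size(); i++) prior_mask[(size_t)pu[i] * n + pv[i]] = 1;

  std::vector<int> ord(P);
  for (int gen = 1; gen <= max_gen; gen++) {
    for (int i = 0; i < P; i++) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return fit[a] > fit[b]; });
    int best_i = ord[0];
    const Adj& badj = pop[best_i];
    int nprior = 0, nedges = 0;
    for (size_t e = 0; e < badj.size(); e++) {
      if (badj[e]) { nedges++; if (prior_mask[e]) nprior++; }
    }
    tr_gen.push_back(gen);
    tr_fit.push_back(fit[best_i]);
    tr_prior.push_back(nprior);
    tr_edges.push_back(nedges);
    best_hist.push_back(fit[best_i]);
    if ((int)best_hist.size() > plateau_window) {
      double ref = best_hist[best_hist.size() - 1 - plateau_window];
      double scale = std::abs(ref) > 1 ? std::abs(ref) : 1.0;
      if (best_hist.back() - ref <= plateau_tol * scale) break;
    }
    if (gen == max_gen) break;

    // parent pools per offspring group: (1x1), (1x2), (2x3); group 4 fresh
    std::vector<Adj> newpop(P);
    std::vector<std::pair<int, int> > pools;
    int off1 = 0, off2 = gs[0], off3 = gs[0] + gs[1];
    pools.push_back(std::make_pair(0, 0));
    pools.push_back(std::make_pair(0, 1));
    pools.push_back(std::make_pair(1, 2));
    int offs[3] = {off1, off2, off3};
    int slot = 0;
    for (int g = 0; g < 3; g++) {
      int pa_off = offs[pools[g].first], pa_n = gs[pools[g].first];
      int pb_off = offs[pools[g].second], pb_n = gs[pools[g].second];
      for (int j = 0; j < gs[g]; j++) {
        int ia = ord[pa_off + ri(pa_n)];
        int ib = ord[pb_off + ri(pb_n)];
        Adj child = crossover_enabled ? crossover(pop[ia], pop[ib], n, max_parents)
                                      : pop[ia];
        mutate(child, n, mut_rates[g], max_parents, msrc);
        newpop[slot++] = child;
      }
    }
    for (int j = 0; j < gs[3]; j++) {
      Adj fresh = init_adj_cpp(n, pu, pv, pp, poisson_rate, isrc, max_parents);
      mutate(fresh, n, mut_rates[3], max_parents, msrc);
      newpop[slot++] = fresh;
    }
    newpop[P - 1] = badj;  // elitism
    pop.swap(newpop);
    for (int i = 0; i < P; i++) fit[i] = sc.net_score(pop[i]);
  }

  int best_i = 0;
  for (int i = 1; i < P; i++) if (fit[i] > fit[best_i]) best_i = i;
  int T = (int)tr_gen.size();
  NumericMatrix trace(T, 4);
  for (int t = 0; t < T; t++) {
    trace(t, 0) = tr_gen[t];
    trace(t, 1) = tr_fit[t];
    trace(t, 2) = tr_prior[t];
    trace(t, 3) = tr_edges[t];
  }
  return List::create(_["best"] = as_matrix(pop[best_i], n),
                      _["best_fitness"] = fit[best_i],
                      _["trace"] = trace,
                      _["fitness"] = NumericVector(fit.begin(), fit.end()));
}

// Structure MCMC with single-edge add/delete/reverse moves.  An ordered
// pair (u, v) is drawn uniformly; an absent edge proposes an addition, a
// present edge proposes deletion or reversal with equal probability.  The
// Hastings correction accounts for the add/delete asymmetry (1/2 and 2
// respectively); reversals are symmetric.  Cycle- or cap-violating
// proposals are rejected, which preserves detailed balance.
// [[Rcpp::export]]
List cpp_mcmc(IntegerMatrix data, int k, LogicalMatrix seed_adj,
              NumericMatrix logL, double ess, int max_parents,
              int n_steps, double temperature, double burn_frac) {
  int n = data.nrow();
  Scorer sc;
  sc.x = INTEGER(data);
  sc.n = n;
  sc.ns = data.ncol();
  sc.k = k;
  sc.ess = ess;
  sc.logL = REAL(logL);
  const double* L = REAL(logL);

  Adj adj = as_adj(seed_adj);
  std::vector<int> indeg = indegrees(adj, n);
  std::vector<double> fam(n);
  for (int v = 0; v < n; v++) fam[v] = sc.family_of(adj, v);
  double score = 0.0;
  for (int v = 0; v < n; v++) score += fam[v];
  for (int u = 0; u < n; u++)
    for (int v = 0; v < n; v++)
      if (adj[(size_t)u * n + v]) score += L[u + (size_t)n * v];

  double best_score = score;
  Adj best = adj;
  int burn = (int)(burn_frac * n_steps);
  std::vector<double> freq((size_t)n * n, 0.0);
  long kept = 0, accepted = 0;

  for (int step = 0; step < n_steps; step++) {
    int u = ri(n);
    int v = ri(n - 1);
    if (v >= u) v++;
    size_t euv = (size_t)u * n + v;
    if (!adj[euv]) {
      // propose add u->v (Hastings correction 1/2)
      bool valid = indeg[v] < max_parents && !reachable(adj, n, v, u);
      if (valid) {
        adj[euv] = 1;
        double fnew = sc.family_of(adj, v);
        adj[euv] = 0;
        double delta = fnew - fam[v] + L[u + (size_t)n * v];
        if (unif_rand() < 0.5 * std::exp(delta / temperature)) {
          adj[euv] = 1;
          indeg[v]++;
          fam[v] = fnew;
          score += delta;
          accepted++;
        }
      }
    } else if (unif_rand() < 0.5) {
      // propose delete u->v (Hastings correction 2)
      adj[euv] = 0;
      double fnew = sc.family_of(adj, v);
      double delta = fnew - fam[v] - L[u + (size_t)n * v];
      if (unif_rand() < 2.0 * std::exp(delta / temperature)) {
        indeg[v]--;
        fam[v] = fnew;
        score += delta;
        accepted++;
      } else {
        adj[euv] = 1;
      }
    } else {
      // propose reverse u->v to v->u (symmetric)
      adj[euv] = 0;
      bool valid = indeg[u] < max_parents && !reachable(adj, n, u, v);
      if (!valid) {
        adj[euv] = 1;
      } else {
        size_t evu = (size_t)v * n + u;
        double fv = sc.family_of(adj, v);
        adj[evu] = 1;
        double fu = sc.family_of(adj, u);
        double delta = (fv - fam[v]) + (fu - fam[u]) +
          L[v + (size_t)n * u] - L[u + (size_t)n * v];
        if (unif_rand() < std::exp(delta / temperature)) {
          indeg[v]--;
          indeg[u]++;
          fam[v] = fv;
          fam[u] = fu;
          score += delta;
          accepted++;
        } else {
          adj[evu] = 0;
          adj[euv] = 1;
        }
      }
    }
    if (score > best_score) {
      best_score = score;
      best = adj;
    }
    if (step >= burn) {
      kept++;
      for (size_t e = 0; e < adj.size(); e++) if (adj[e]) freq[e] += 1.0;
    }
  }
  NumericMatrix fq(n, n);
  if (kept > 0)
    for (int u = 0; u < n; u++)
      for (int v = 0; v < n; v++) fq(u, v) = freq[(size_t)u * n + v] / kept;
  return List::create(_["freq"] = fq, _["best"] = as_matrix(best, n),
                      _["best_score"] = best_score,
                      _["final_score"] = score,
                      _["accept_rate"] = (double)accepted / n_steps);
}
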