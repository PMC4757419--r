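// Monte-Carlo swap engines. All randomness comes from R's RNG stream
// (unif_rand), so set.seed() in R makes every run reproducible.
//
// Degree assortativity r_kk is the Pearson correlation of the degrees at the
// two ends of a random edge. Under degree-preserving double-edge swaps the
// neighbor degree distribution q(k) is fixed, so r_kk depends on the edge set
// only through T = sum over edges of k_u * k_v:
//     r_kk = (T/M - mu_q^2) / sigma_q^2.
// Each swap changes T by an O(1) delta; tests compare this incremental value
// against a from-scratch recomputation.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

namespace {

struct EdgeSystem {
  int n, m;
  std::vector<int> ea, eb;
  std::vector<std::unordered_set<int>> adj;
  std::vector<double> deg;
  double mu_q, var_q, T;

  EdgeSystem(const IntegerMatrix& el, const IntegerVector& degv) {
    n = degv.size();
    m = el.nrow();
    ea.resize(m); eb.resize(m);
    adj.assign(n, {});
    deg.assign(degv.begin(), degv.end());
    double s1 = 0.0, s2 = 0.0;
    T = 0.0;
    for (int i = 0; i < m; ++i) {
      int a = el(i, 0), b = el(i, 1);
      ea[i] = a; eb[i] = b;
      adj[a].insert(b); adj[b].insert(a);
      double ka = deg[a], kb = deg[b];
      s1 += ka + kb; s2 += ka * ka + kb * kb;
      T += ka * kb;
    }
    mu_q = s1 / (2.0 * m);
    var_q = s2 / (2.0 * m) - mu_q * mu_q;
  }

  double r_of(double Tval) const { return (Tval / m - mu_q * mu_q) / var_q; }
  double r() const { return r_of(T); }

  bool has_edge(int u, int v) const { return adj[u].count(v) > 0; }

  // replace edges (a,b),(c,d) by (a,u),(b,v) where {u,v} = {c,d}
  void apply(int i, int j, int u, int v, double dT) {
    int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
    adj[a].erase(b); adj[b].erase(a);
    adj[c].erase(d); adj[d].erase(c);
    adj[a].insert(u); adj[u].insert(a);
    adj[b].insert(v); adj[v].insert(b);
    ea[i] = a; eb[i] = u;
    ea[j] = b; eb[j] = v;
    T += dT;
  }

  IntegerMatrix edges() const {
    IntegerMatrix out(m, 2);
    for (int i = 0; i < m; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
    return out;
  }
};

inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

} // namespace

// [[Rcpp::export]]
List cpp_rewire_assort(IntegerMatrix el, IntegerVector deg, double target_r,
                       double tol, int max_attempts) {
  EdgeSystem es(el, deg);
  if (es.var_q <= 0) stop("assortativity undefined: all edge-end degrees equal");
  long long accepted = 0, attempts = 0;
  double cur = es.r();

  while (attempts < max_attempts && std::fabs(cur - target_r) > tol) {
    ++attempts;
    int i = rand_below(es.m), j = rand_below(es.m);
    if (i == j) continue;
    int a = es.ea[i], b = es.eb[i], c = es.ea[j], d = es.eb[j];
    if (a == c || a == d || b == c || b == d) continue;
    double ka = es.deg[a], kb = es.deg[b], kc = es.deg[c], kd = es.deg[d];

    // pairing 1: (a,c),(b,d); pairing 2: (a,d),(b,c)
    bool ok1 = !es.has_edge(a, c) && !es.has_edge(b, d);
    bool ok2 = !es.has_edge(a, d) && !es.has_edge(b, c);
    double dT1 = ka * kc + kb * kd - ka * kb - kc * kd;
    double dT2 = ka * kd + kb * kc - ka * kb - kc * kd;
    double cur_dist = std::fabs(cur - target_r);
    double best = cur_dist;
    int which = 0;
    if (ok1) {
      double d1 = std::fabs(es.r_of(es.T + dT1) - target_r);
      if (d1 < best) { best = d1; which = 1; }
    }
    if (ok2) {
      double d2 = std::fabs(es.r_of(es.T + dT2) - target_r);
      if (d2 < best) { best = d2; which = 2; }
    }
    if (which == 1)      es.apply(i, j, c, d, dT1);
    else if (which == 2) es.apply(i, j, d, c, dT2);
    else continue;
    ++accepted;
    cur = es.r();
  }

  return List::create(
    _["edges"] = es.edges(), _["achieved_r"] = cur,
    _["accepted"] = (double)accepted, _["attempts"] = (double)attempts,
    _["target_reached"] = std::fabs(cur - target_r) <= tol);
}

// [[Rcpp::export]]
List cpp_rewire_ekk(IntegerMatrix el, IntegerVector deg, double r_tol,
                    int max_attempts) {
  EdgeSystem es(el, deg);
  if (es.var_q <= 0) stop("assortativity undefined: all edge-end degrees equal");
  const double r0 = es.r();
  long long accepted = 0, attempts = 0;

  while (attempts < max_attempts) {
    ++attempts;
    int i = rand_below(es.m), j = rand_below(es.m);
    if (i == j) continue;
    int a = es.ea[i], b = es.eb[i], c = es.ea[j], d = es.eb[j];
    if (a == c || a == d || b == c || b == d) continue;
    double ka = es.deg[a], kb = es.deg[b], kc = es.deg[c], kd = es.deg[d];

    // an e(k,k') entry changes iff the multiset of degree pairs changes
    auto pairkey = [](double x, double y) {
      return x < y ? std::make_pair(x, y) : std::make_pair(y, x);
    };
    auto norm2 = [&](std::pair<double,double> p, std::pair<double,double> q) {
      return p < q ? std::make_pair(p, q) : std::make_pair(q, p);
    };
    auto old_pairs = norm2(pairkey(ka, kb), pairkey(kc, kd));

    bool ok1 = !es.has_edge(a, c) && !es.has_edge(b, d);
    bool ok2 = !es.has_edge(a, d) && !es.has_edge(b, c);
    double dT1 = ka * kc + kb * kd - ka * kb - kc * kd;
    double dT2 = ka * kd + kb * kc - ka * kb - kc * kd;
    bool acc1 = ok1 && norm2(pairkey(ka, kc), pairkey(kb, kd)) != old_pairs &&
                std::fabs(es.r_of(es.T + dT1) - r0) <= r_tol;
    bool acc2 = ok2 && norm2(pairkey(ka, kd), pairkey(kb, kc)) != old_pairs &&
                std::fabs(es.r_of(es.T + dT2) - r0) <= r_tol;
    if (acc1 && acc2) { if (unif_rand() < 0.5) acc2 = false; else acc1 = false; }
    if (acc1)      es.apply(i, j, c, d, dT1);
    else if (acc2) es.apply(i, j, d, c, dT2);
    else continue;
    ++accepted;
  }

  return List::create(
    _["edges"] = es.edges(), _["achieved_r"] = es.r(),
    _["initial_r"] = r0, _["accepted"] = (double)accepted,
    _["attempts"] = (double)attempts);
}

// [[Rcpp::export]]
List cpp_swap_attrs(IntegerVector deg, IntegerVector x, double target_rho,
                    double tol, double max_iter, double stall_limit) {
  const int n = deg.size();
  std::vector<int> act, inact;
  act.reserve(n); inact.reserve(n);
  double sumA = 0.0, sumK = 0.0, sumK2 = 0.0;
  for (int i = 0; i < n; ++i) {
    sumK += deg[i]; sumK2 += (double)deg[i] * deg[i];
    if (x[i] == 1) { act.push_back(i); sumA += deg[i]; }
    else inact.push_back(i);
  }
  const int nA = act.size();
  if (nA == 0 || nA == n) stop("need at least one active and one inactive node (sigma_x = 0)");
  const double meanK = sumK / n;
  const double sk = std::sqrt(sumK2 / n - meanK * meanK);
  if (sk <= 0) stop("degree-regular graph: rho_kx undefined (sigma_k = 0)");
  const double p1 = (double)nA / n;
  const double sx = std::sqrt(p1 * (1.0 - p1));
  const double cfac = p1 / (sx * sk);
  auto rho_of = [&](double s) { return cfac * (s / nA - meanK); };

  double rho = rho_of(sumA);
  double iters = 0, acceptedn = 0;
  long long stall = 0;

  while (iters < max_iter && std::fabs(rho - target_rho) > tol &&
         stall < (long long)stall_limit) {
    ++iters;
    int ia = rand_below(nA), ii = rand_below(n - nA);
    int v1 = act[ia], v0 = inact[ii];
    double cand = rho_of(sumA + deg[v0] - deg[v1]);
    if (std::fabs(cand - target_rho) < std::fabs(rho - target_rho)) {
      act[ia] = v0; inact[ii] = v1;
      sumA += deg[v0] - deg[v1];
      rho = cand;
      ++acceptedn;
      stall = 0;
    } else {
      ++stall;
    }
  }

  IntegerVector out(n, 0);
  for (int v : act) out[v] = 1;
  return List::create(
    _["x"] = out, _["achieved_rho"] = rho, _["iterations"] = iters,
    _["accepted"] = acceptedn,
    _["converged"] = std::fabs(rho - target_rho) <= tol,
    _["stalled"] = stall >= (long long)stall_limit);
}
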