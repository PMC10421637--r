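#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All randomness flows through R's RNG so set.seed() on the R side gives
// bit-for-bit reproducible sample sets.

static inline int rand_site(int n) {
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

static std::vector<std::vector<int> > build_adj(const IntegerMatrix& edges, int n) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  return adj;
}

static inline void heatbath_ising(std::vector<int>& s, int i, double u,
                                  double beta, const NumericVector& h,
                                  const std::vector<std::vector<int> >& adj) {
  double f = h[i];
  const std::vector<int>& nb = adj[i];
  for (size_t k = 0; k < nb.size(); ++k) f += s[nb[k]];
  double p_up = 1.0 / (1.0 + std::exp(-2.0 * beta * f));
  s[i] = (u < p_up) ? 1 : -1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_ising(IntegerMatrix edges, int n, double beta,
                              NumericVector h, int K, int burn_in,
                              int thinning, bool relabel) {
  std::vector<std::vector<int> > adj = build_adj(edges, n);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = (unif_rand() < 0.5) ? 1 : -1;
  IntegerMatrix out(K, n);
  long sweeps = (long)burn_in;
  for (long t = 0; t < sweeps * n; ++t)
    heatbath_ising(s, rand_site(n), unif_rand(), beta, h, adj);
  for (int k = 0; k < K; ++k) {
    for (long t = 0; t < (long)thinning * n; ++t)
      heatbath_ising(s, rand_site(n), unif_rand(), beta, h, adj);
    if (relabel && unif_rand() < 0.5)
      for (int i = 0; i < n; ++i) s[i] = -s[i];
    for (int i = 0; i < n; ++i) out(k, i) = s[i];
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_potts(IntegerMatrix edges, int n, int q, double beta,
                              int K, int burn_in, int thinning, bool relabel) {
  std::vector<std::vector<int> > adj = build_adj(edges, n);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = rand_site(q);
  std::vector<double> w(q);
  std::vector<int> cnt(q), perm(q);
  IntegerMatrix out(K, n);
  long total = ((long)burn_in + (long)K * thinning) * n;
  int k = 0;
  long retain_at = (long)burn_in * n + (long)thinning * n;
  for (long t = 1; t <= total; ++t) {
    int i = rand_site(n);
    std::fill(cnt.begin(), cnt.end(), 0);
    const std::vector<int>& nb = adj[i];
    for (size_t m = 0; m < nb.size(); ++m) cnt[s[nb[m]]]++;
    double z = 0.0;
    for (int a = 0; a < q; ++a) { w[a] = std::exp(beta * cnt[a]); z += w[a]; }
    double u = unif_rand() * z, acc = 0.0;
    int pick = q - 1;
    for (int a = 0; a < q; ++a) { acc += w[a]; if (u < acc) { pick = a; break; } }
    s[i] = pick;
    if (t == retain_at) {
      if (relabel) { // uniform random permutation of the q labels
        for (int a = 0; a < q; ++a) perm[a] = a;
        for (int a = q - 1; a > 0; --a) {
          int b = rand_site(a + 1);
          int tmp = perm[a]; perm[a] = perm[b]; perm[b] = tmp;
        }
        for (int v = 0; v < n; ++v) s[v] = perm[s[v]];
      }
      for (int v = 0; v < n; ++v) out(k, v) = s[v] + 1;
      ++k;
      retain_at += (long)thinning * n;
      if (k % 256 == 0) Rcpp::checkUserInterrupt();
      if (k == K) break;
    }
  }
  return out;
}

// Monotone coupling from the past for the ferromagnetic Ising model.
// Heat-bath updates preserve the partial order on configurations, so the
// chains started all-up and all-down sandwich every trajectory; their
// coalescence at time 0 certifies an exact draw from the Boltzmann
// distribution.  Randomness for times [-T, 0) is fixed once and reused
// verbatim when the starting time is pushed further into the past.
// [[Rcpp::export]]
List cpp_cftp_ising(IntegerMatrix edges, int n, double beta, NumericVector h,
                    int K, double max_updates, bool check_sandwich) {
  std::vector<std::vector<int> > adj = build_adj(edges, n);
  IntegerMatrix out(K, n);
  NumericVector updates_used(K);
  bool sandwich_ok = true;
  std::vector<int> up(n), dn(n);
  for (int k = 0; k < K; ++k) {
    std::vector<int> sites;
    std::vector<double> us;
    long target = n; // first epoch: one sweep
    for (;;) {
      long add = target - (long)sites.size();
      // fresh randomness belongs to the more distant past: prepend
      std::vector<int> ns(add);
      std::vector<double> nu(add);
      for (long t = 0; t < add; ++t) { ns[t] = rand_site(n); nu[t] = unif_rand(); }
      sites.insert(sites.begin(), ns.begin(), ns.end());
      us.insert(us.begin(), nu.begin(), nu.end());
      for (int i = 0; i < n; ++i) { up[i] = 1; dn[i] = -1; }
      for (long t = 0; t < target; ++t) {
        int i = sites[t];
        heatbath_ising(up, i, us[t], beta, h, adj);
        heatbath_ising(dn, i, us[t], beta, h, adj);
        if (check_sandwich && dn[i] > up[i]) sandwich_ok = false;
      }
      bool coalesced = true;
      for (int i = 0; i < n; ++i) if (up[i] != dn[i]) { coalesced = false; break; }
      if (coalesced) {
        for (int i = 0; i < n; ++i) out(k, i) = up[i];
        updates_used[k] = (double)target;
        break;
      }
      if (2.0 * (double)target > max_updates)
        stop("coupling from the past did not coalesce within %g single-site updates (draw %d); the chain mixes too slowly at this temperature -- use sample_gibbs() or raise max_sweeps", max_updates, k + 1);
      target *= 2;
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["samples"] = out,
                      _["updates_used"] = updates_used,
                      _["sandwich_ok"] = sandwich_ok);
}
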