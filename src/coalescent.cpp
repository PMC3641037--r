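#include <Rcpp.h>
#include <set>
#include <cstdint>
using namespace Rcpp;

// Neutral constant-size Kingman coalescent with infinite-sites mutation.
// For each replicate returns the number of distinct haplotypes k and the
// mean pairwise difference pi. Mutations land on branches as
// Poisson(theta/2 * length); a tip's haplotype is the set of mutated
// branches on its root path, identified exactly via XOR of per-branch
// random 64-bit keys (order-independent). Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix coalescent_kpi_cpp(int n, double theta, int reps) {
  NumericMatrix out(reps, 2);
  int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes), active(n);
  std::vector<double> blen(n_nodes), t_node(n_nodes);
  std::vector<int> desc(n_nodes);
  std::vector<uint64_t> key(n_nodes), sig(n_nodes);

  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < n; ++i) active[i] = i;
    std::fill(t_node.begin(), t_node.end(), 0.0);
    std::fill(parent.begin(), parent.end(), -1);
    int n_active = n, nxt = n;
    double t_cur = 0.0;
    while (n_active > 1) {
      double rate = n_active * (n_active - 1) / 2.0;
      t_cur += R::rexp(1.0) / rate;
      int a = (int)(unif_rand() * n_active);
      int b = (int)(unif_rand() * (n_active - 1));
      if (b >= a) ++b;
      int ca = active[a], cb = active[b];
      parent[ca] = nxt; parent[cb] = nxt;
      blen[ca] = t_cur - t_node[ca];
      blen[cb] = t_cur - t_node[cb];
      t_node[nxt] = t_cur;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      active[hi] = active[n_active - 1];
      active[lo] = nxt;
      --n_active;
      ++nxt;
    }
    // descendant counts (nodes created in increasing order)
    for (int v = 0; v < n_nodes; ++v) desc[v] = v < n ? 1 : 0;
    for (int v = 0; v < n_nodes - 1; ++v) desc[parent[v]] += desc[v];
    // mutations per branch and pi
    double diff_sum = 0.0;
    for (int v = 0; v < n_nodes - 1; ++v) {
      int m = (int)R::rpois(theta / 2.0 * blen[v]);
      if (m > 0) {
        uint64_t k1 = (uint64_t)(unif_rand() * 4294967296.0);
        uint64_t k2 = (uint64_t)(unif_rand() * 4294967296.0);
        key[v] = (k1 << 32) ^ k2 ^ 1ULL;
        diff_sum += (double)m * desc[v] * (n - desc[v]);
      } else {
        key[v] = 0ULL;
      }
    }
    // haplotype signatures top-down (parent index always > child index)
    sig[n_nodes - 1] = 0ULL;
    for (int v = n_nodes - 2; v >= 0; --v)
      sig[v] = sig[parent[v]] ^ key[v];
    std::set<uint64_t> uniq(sig.begin(), sig.begin() + n);
    out(r, 0) = (double)uniq.size();
    out(r, 1) = diff_sum / (n * (n - 1) / 2.0);
  }
  return out;
}
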