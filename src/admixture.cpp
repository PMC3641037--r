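#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the haploid Bernoulli admixture model of dominant
// marker bands:
//   x_il ~ Bernoulli(p_{z_il, l}),  z_il ~ Categorical(q_i),
//   q_i ~ Dirichlet(alpha * 1_K),   p_kl ~ Beta(1, 1).
// Conjugate updates throughout; missing bands (NA) contribute nothing to
// the likelihood and leave z_il driven by q alone. The data log-likelihood
// (z integrated out) is recorded for post-burn-in sweeps. Uses R's RNG so
// results are reproducible via set.seed().
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix x, int K, int burn_in, int sweeps,
                         double alpha) {
  const int n = x.nrow(), L = x.ncol();
  const int total = burn_in + sweeps;
  // column-major copies with missing coded -1
  std::vector<signed char> xv((size_t)n * L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i) {
      int v = x(i, l);
      xv[(size_t)l * n + i] = (v == NA_INTEGER) ? -1 : (signed char)v;
    }
  std::vector<double> q((size_t)n * K, 1.0 / K); // q[i*K + k]
  std::vector<double> p((size_t)K * L, 0.5);     // p[l*K + k]
  std::vector<signed char> z((size_t)n * L);     // z[l*n + i]
  std::vector<double> q_sum((size_t)n * K, 0.0), p_sum((size_t)K * L, 0.0);
  std::vector<double> n1((size_t)K * L), n0((size_t)K * L);
  std::vector<double> m(K), prob(K);
  NumericVector lnl_trace(sweeps);

  for (size_t c = 0; c < z.size(); ++c)
    z[c] = (signed char)(unif_rand() * K);

  for (int sweep = 0; sweep < total; ++sweep) {
    // p | z, x
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      const size_t off = (size_t)l * n, poff = (size_t)l * K;
      for (int i = 0; i < n; ++i) {
        int xi = xv[off + i];
        if (xi < 0) continue;
        if (xi == 1) n1[poff + z[off + i]] += 1.0;
        else n0[poff + z[off + i]] += 1.0;
      }
    }
    for (size_t c = 0; c < p.size(); ++c)
      p[c] = R::rbeta(1.0 + n1[c], 1.0 + n0[c]);
    // q | z
    for (int i = 0; i < n; ++i) {
      std::fill(m.begin(), m.end(), 0.0);
      for (int l = 0; l < L; ++l) m[z[(size_t)l * n + i]] += 1.0;
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + m[k], 1.0);
        if (g <= 0) g = 1e-300;
        prob[k] = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) q[(size_t)i * K + k] = prob[k] / s;
    }
    // z | q, p, x  (and the integrated-z log-likelihood on kept sweeps)
    const bool keep = sweep >= burn_in;
    double lnl = 0.0;
    for (int l = 0; l < L; ++l) {
      const size_t off = (size_t)l * n, poff = (size_t)l * K;
      for (int i = 0; i < n; ++i) {
        const int xi = xv[off + i];
        const double *qi = &q[(size_t)i * K];
        double s = 0.0;
        if (xi < 0) {
          for (int k = 0; k < K; ++k) { prob[k] = qi[k]; s += prob[k]; }
        } else if (xi == 1) {
          for (int k = 0; k < K; ++k) { prob[k] = qi[k] * p[poff + k]; s += prob[k]; }
        } else {
          for (int k = 0; k < K; ++k) { prob[k] = qi[k] * (1.0 - p[poff + k]); s += prob[k]; }
        }
        double u = unif_rand() * s, acc = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += prob[k];
          if (u <= acc) { pick = k; break; }
        }
        z[off + i] = (signed char)pick;
        if (keep && xi >= 0) lnl += log(s > 1e-300 ? s : 1e-300);
      }
    }
    if (keep) {
      lnl_trace[sweep - burn_in] = lnl;
      for (size_t c = 0; c < q.size(); ++c) q_sum[c] += q[c];
      for (size_t c = 0; c < p.size(); ++c) p_sum[c] += p[c];
    }
  }
  NumericMatrix q_out(n, K), p_out(K, L);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q_out(i, k) = q_sum[(size_t)i * K + k] / sweeps;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p_out(k, l) = p_sum[(size_t)l * K + k] / sweeps;
  return List::create(_["q"] = q_out, _["p"] = p_out,
                      _["lnl_trace"] = lnl_trace);
}
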