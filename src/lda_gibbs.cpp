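#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Tokens are passed flattened: word[i] and doc[i] are the 0-based term and
// document of token i, ordered by (doc, term). The sampler integrates out
// phi and theta and resamples each token's topic from
//   p(z_i = k | z_-i, w)  ∝  (n_dk + alpha) (n_kv + beta) / (n_k + V beta)
// with the current token excluded from all counts. Determinism is
// guaranteed by an internal mt19937 stream seeded from `seed`, independent
// of R's RNG state.
//
// phi and theta are posterior-mean estimates averaged over post-burn-in
// sweeps thinned by `sample_lag`; count caches and z are returned from the
// final sweep. When `track_z_marginal` is true, per-token topic frequencies
// over the retained sweeps are accumulated (used for exact-posterior
// comparisons on tiny corpora).

// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector word, IntegerVector doc, int D, int V, int K,
                   double alpha, double beta, int n_iter, int burn_in,
                   int sample_lag, int seed, bool track_z_marginal) {
  const int N = word.size();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  IntegerVector z(N);
  IntegerMatrix n_dk(D, K), n_kv(K, V);
  IntegerVector n_k(K);
  std::vector<int> Nd(D, 0);
  for (int i = 0; i < N; ++i) Nd[doc[i]]++;

  for (int i = 0; i < N; ++i) {
    int k = static_cast<int>(unif(rng) * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    n_dk(doc[i], k)++;
    n_kv(k, word[i])++;
    n_k[k]++;
  }

  NumericMatrix phi_sum(K, V), theta_sum(D, K);
  NumericMatrix z_marg(track_z_marginal ? N : 1, track_z_marginal ? K : 1);
  // pairwise co-assignment frequencies P(z_i == z_j); label-invariant, so
  // they stay informative under topic-label exchangeability
  NumericMatrix z_pair(track_z_marginal ? N : 1, track_z_marginal ? N : 1);
  NumericVector loglik(n_iter);
  std::vector<double> p(K);
  const double Vb = V * beta, Ka = K * alpha;
  int n_samples = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      n_dk(d, k)--; n_kv(k, w)--; n_k[k]--;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        const double pr = (n_dk(d, kk) + alpha) *
          (n_kv(kk, w) + beta) / (n_k[kk] + Vb);
        p[kk] = pr;
        tot += pr;
      }
      double u = unif(rng) * tot, cum = 0.0;
      int knew = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += p[kk];
        if (u <= cum) { knew = kk; break; }
      }
      z[i] = knew;
      n_dk(d, knew)++; n_kv(knew, w)++; n_k[knew]++;
    }

    // held-in log predictive likelihood with current-state estimates
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      double s = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        s += (n_dk(d, kk) + alpha) / (Nd[d] + Ka) *
          (n_kv(kk, w) + beta) / (n_k[kk] + Vb);
      }
      ll += std::log(s);
    }
    loglik[it] = ll;

    if (it >= burn_in && (it - burn_in) % sample_lag == 0) {
      ++n_samples;
      for (int kk = 0; kk < K; ++kk) {
        const double denom = n_k[kk] + Vb;
        for (int v = 0; v < V; ++v) phi_sum(kk, v) += (n_kv(kk, v) + beta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        const double denom = Nd[d] + Ka;
        for (int kk = 0; kk < K; ++kk) theta_sum(d, kk) += (n_dk(d, kk) + alpha) / denom;
      }
      if (track_z_marginal) {
        for (int i = 0; i < N; ++i) z_marg(i, z[i]) += 1.0;
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < N; ++j)
            if (z[i] == z[j]) z_pair(i, j) += 1.0;
      }
    }
  }

  if (n_samples > 0) {
    for (int kk = 0; kk < K; ++kk)
      for (int v = 0; v < V; ++v) phi_sum(kk, v) /= n_samples;
    for (int d = 0; d < D; ++d)
      for (int kk = 0; kk < K; ++kk) theta_sum(d, kk) /= n_samples;
    if (track_z_marginal) {
      for (int i = 0; i < N; ++i)
        for (int kk = 0; kk < K; ++kk) z_marg(i, kk) /= n_samples;
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j) z_pair(i, j) /= n_samples;
    }
  }

  return List::create(
    _["z"] = z, _["n_dk"] = n_dk, _["n_kv"] = n_kv, _["n_k"] = n_k,
    _["phi"] = phi_sum, _["theta"] = theta_sum, _["loglik"] = loglik,
    _["n_samples"] = n_samples,
    _["z_marginal"] = track_z_marginal ? z_marg : NumericMatrix(0, 0),
    _["z_pair"] = track_z_marginal ? z_pair : NumericMatrix(0, 0));
}
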