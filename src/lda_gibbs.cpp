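#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation on a
// cells x bins count matrix. Tokens are (cell, bin) occurrences; the
// sampler keeps the usual cell-topic and topic-bin count tables and
// resamples every token's topic from its collapsed conditional.
// Uses R's RNG so results are reproducible via set.seed().

// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerMatrix counts, int n_topics, double alpha,
                   double beta, int n_iter) {
  const int D = counts.nrow();
  const int V = counts.ncol();
  const int K = n_topics;

  // expand tokens
  std::vector<int> tok_d, tok_v;
  for (int d = 0; d < D; ++d)
    for (int v = 0; v < V; ++v)
      for (int c = 0; c < counts(d, v); ++c) {
        tok_d.push_back(d);
        tok_v.push_back(v);
      }
  const int N = tok_d.size();
  if (N == 0) stop("empty count matrix");

  std::vector<int> z(N);
  IntegerMatrix ndk(D, K), nkv(K, V);
  IntegerVector nk(K), nd(D);
  GetRNGstate();
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk(tok_d[i], k)++;
    nkv(k, tok_v[i])++;
    nk[k]++;
    nd[tok_d[i]]++;
  }

  std::vector<double> p(K);
  NumericVector loglik(n_iter);
  const double Vbeta = V * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = tok_d[i], v = tok_v[i], kold = z[i];
      ndk(d, kold)--; nkv(kold, v)--; nk[kold]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk(d, k) + alpha) * (nkv(k, v) + beta) / (nk[k] + Vbeta);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double acc = p[0];
      while (u > acc && knew < K - 1) acc += p[++knew];
      z[i] = knew;
      ndk(d, knew)++; nkv(knew, v)++; nk[knew]++;
    }
    // collapsed complete-data log likelihood (up to constants shared
    // across K this includes the K-dependent normalizers)
    double ll = K * (lgamma(Vbeta) - V * lgamma(beta)) +
                D * (lgamma(K * alpha) - K * lgamma(alpha));
    for (int k = 0; k < K; ++k) {
      for (int v = 0; v < V; ++v) ll += lgamma(nkv(k, v) + beta);
      ll -= lgamma(nk[k] + Vbeta);
    }
    for (int d = 0; d < D; ++d) {
      for (int k = 0; k < K; ++k) ll += lgamma(ndk(d, k) + alpha);
      ll -= lgamma(nd[d] + K * alpha);
    }
    loglik[it] = ll;
  }
  PutRNGstate();

  NumericMatrix theta(D, K), phi(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk(d, k) + alpha) / (nd[d] + K * alpha);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v)
      phi(k, v) = (nkv(k, v) + beta) / (nk[k] + Vbeta);

  // per-token predictive log likelihood -> perplexity
  double ll_word = 0.0;
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += theta(tok_d[i], k) * phi(k, tok_v[i]);
    ll_word += std::log(s);
  }

  return List::create(_["theta"] = theta, _["phi"] = phi,
                      _["loglik"] = loglik, _["n_tokens"] = N,
                      _["perplexity"] = std::exp(-ll_word / N));
}
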