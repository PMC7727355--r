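#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// doc/word are 0-based token vectors (one entry per token occurrence).
// Returns the raw count tables after the final sweep; posterior means are
// formed on the R side so the smoothing policy lives in one place.
//
// The RNG is a private mt19937_64 seeded from `seed`, so results are
// bitwise reproducible and independent of R's RNG state.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_words, int n_topics,
                   double alpha, double beta, int n_iter,
                   unsigned int seed) {
  const int n_tok = doc.size();
  const int K = n_topics;
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(n_tok);
  std::vector<double> ndk((size_t)n_docs * K, 0.0);
  std::vector<double> nkw((size_t)K * n_words, 0.0);
  std::vector<double> nk(K, 0.0);

  // random init
  for (int i = 0; i < n_tok; ++i) {
    int k = (int)(unif(rng) * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k] += 1.0;
    nkw[(size_t)k * n_words + word[i]] += 1.0;
    nk[k] += 1.0;
  }

  std::vector<double> p(K);
  const double Vbeta = n_words * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n_tok; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk[(size_t)d * K + k] -= 1.0;
      nkw[(size_t)k * n_words + w] -= 1.0;
      nk[k] -= 1.0;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        tot += (ndk[(size_t)d * K + j] + alpha) *
               (nkw[(size_t)j * n_words + w] + beta) / (nk[j] + Vbeta);
        p[j] = tot;
      }
      const double u = unif(rng) * tot;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;
      z[i] = k;
      ndk[(size_t)d * K + k] += 1.0;
      nkw[(size_t)k * n_words + w] += 1.0;
      nk[k] += 1.0;
    }
  }

  NumericMatrix ndk_out(n_docs, K), nkw_out(K, n_words);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < K; ++k) ndk_out(d, k) = ndk[(size_t)d * K + k];
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < n_words; ++w) nkw_out(k, w) = nkw[(size_t)k * n_words + w];
  return List::create(_["ndk"] = ndk_out, _["nkw"] = nkw_out,
                      _["nk"] = NumericVector(nk.begin(), nk.end()));
}
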