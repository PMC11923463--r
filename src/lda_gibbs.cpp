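#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. Documents are 0-based word-id vectors.
// Uses R's RNG so fits are deterministic under set.seed().

static inline int sample_topic(const std::vector<double>& p, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += p[k];
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// joint log p(w, z) up to constants in alpha/beta terms that do not depend
// on the assignment; tracked per sweep as a convergence monitor
static double joint_loglik(const IntegerMatrix& ndk, const IntegerMatrix& nkw,
                           const IntegerVector& nk, const IntegerVector& dlen,
                           double alpha, double beta, int K, int V) {
  double ll = 0.0;
  int D = ndk.nrow();
  for (int k = 0; k < K; ++k) {
    for (int w = 0; w < V; ++w)
      if (nkw(k, w) > 0) ll += lgamma(nkw(k, w) + beta) - lgamma(beta);
    ll += lgamma(V * beta) - lgamma(nk[k] + V * beta);
  }
  for (int d = 0; d < D; ++d) {
    for (int k = 0; k < K; ++k)
      if (ndk(d, k) > 0) ll += lgamma(ndk(d, k) + alpha) - lgamma(alpha);
    ll += lgamma(K * alpha) - lgamma(dlen[d] + K * alpha);
  }
  return ll;
}

// [[Rcpp::export]]
List gibbs_fit_cpp(List docs, int K, int V, double alpha, double beta,
                   int n_iters) {
  int D = docs.size();
  IntegerMatrix ndk(D, K);
  IntegerMatrix nkw(K, V);
  IntegerVector nk(K);
  IntegerVector dlen(D);
  std::vector<IntegerVector> w(D);
  std::vector<IntegerVector> z(D);

  for (int d = 0; d < D; ++d) {
    w[d] = as<IntegerVector>(docs[d]);
    int n = w[d].size();
    dlen[d] = n;
    z[d] = IntegerVector(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ndk(d, k)++;
      nkw(k, w[d][i])++;
      nk[k]++;
    }
  }

  NumericVector loglik(n_iters);
  std::vector<double> p(K);
  for (int it = 0; it < n_iters; ++it) {
    for (int d = 0; d < D; ++d) {
      int n = dlen[d];
      for (int i = 0; i < n; ++i) {
        int wi = w[d][i], zi = z[d][i];
        ndk(d, zi)--; nkw(zi, wi)--; nk[zi]--;
        for (int k = 0; k < K; ++k) {
          p[k] = (ndk(d, k) + alpha) * (nkw(k, wi) + beta) / (nk[k] + V * beta);
        }
        int knew = sample_topic(p, K);
        z[d][i] = knew;
        ndk(d, knew)++; nkw(knew, wi)++; nk[knew]++;
      }
    }
    loglik[it] = joint_loglik(ndk, nkw, nk, dlen, alpha, beta, K, V);
  }

  List zout(D);
  for (int d = 0; d < D; ++d) zout[d] = z[d];
  return List::create(_["n_dk"] = ndk, _["n_kw"] = nkw, _["n_k"] = nk,
                      _["z"] = zout, _["loglik"] = loglik);
}

// Fold-in: sample topic assignments for held-out documents with the
// topic-word distributions frozen; returns smoothed document-topic
// estimates (D x K).
// [[Rcpp::export]]
NumericMatrix gibbs_foldin_cpp(List docs, NumericMatrix phi, double alpha,
                               int n_iters) {
  int D = docs.size();
  int K = phi.nrow();
  NumericMatrix theta(D, K);
  std::vector<double> p(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector w = docs[d];
    int n = w.size();
    std::vector<int> mk(K, 0);
    std::vector<int> z(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[i] = k;
      mk[k]++;
    }
    for (int it = 0; it < n_iters; ++it) {
      for (int i = 0; i < n; ++i) {
        int wi = w[i];
        mk[z[i]]--;
        for (int k = 0; k < K; ++k) p[k] = (mk[k] + alpha) * phi(k, wi);
        int knew = sample_topic(p, K);
        z[i] = knew;
        mk[knew]++;
      }
    }
    for (int k = 0; k < K; ++k) theta(d, k) = (mk[k] + alpha) / (n + K * alpha);
  }
  return theta;
}
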