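#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampling for multi-field LDA: one shared per-document
// (disease) topic distribution theta, independent per-modality topic-gene
// distributions phi_m. Tokens are (doc, modality, word) triples; words are
// indexed within each modality's own vocabulary.
//
// Sampling distribution for token i with doc d, modality m, word w:
//   P(z_i = k | .) propto (n_dk + alpha) * (n_mkw + beta_m) / (n_mk + beta_m * V_m)
//
// Point estimates are means over post-burn-in sweeps. Randomness comes from
// R's RNG (unif_rand), so results are reproducible under set.seed().

static inline int sample_cat(const std::vector<double>& p, int K, double total) {
  double u = unif_rand() * total;
  double cum = 0.0;
  for (int k = 0; k < K; ++k) {
    cum += p[k];
    if (u <= cum) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List gibbs_fit_cpp(IntegerVector doc, IntegerVector mod, IntegerVector word,
                   int D, int M, IntegerVector V, int K,
                   double alpha, NumericVector beta,
                   int n_iter, int burn_in) {
  const int N = doc.size();
  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0);
  std::vector<double> nd(D, 0.0);
  std::vector<std::vector<double>> nkw(M), nk(M);
  for (int m = 0; m < M; ++m) {
    nkw[m].assign((size_t)K * V[m], 0.0);
    nk[m].assign(K, 0.0);
  }

  // random initial assignment
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k] += 1.0;
    nd[doc[i]] += 1.0;
    nkw[mod[i]][(size_t)k * V[mod[i]] + word[i]] += 1.0;
    nk[mod[i]][k] += 1.0;
  }

  std::vector<double> theta_acc((size_t)D * K, 0.0);
  std::vector<std::vector<double>> phi_acc(M);
  for (int m = 0; m < M; ++m) phi_acc[m].assign((size_t)K * V[m], 0.0);
  int n_samples = 0;

  std::vector<double> p(K);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], m = mod[i], w = word[i];
      const int kold = z[i];
      const double bm = beta[m], Vm = (double)V[m];
      ndk[(size_t)d * K + kold] -= 1.0;
      nkw[m][(size_t)kold * V[m] + w] -= 1.0;
      nk[m][kold] -= 1.0;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk[(size_t)d * K + k] + alpha) *
               (nkw[m][(size_t)k * V[m] + w] + bm) / (nk[m][k] + bm * Vm);
        total += p[k];
      }
      const int knew = sample_cat(p, K, total);
      z[i] = knew;
      ndk[(size_t)d * K + knew] += 1.0;
      nkw[m][(size_t)knew * V[m] + w] += 1.0;
      nk[m][knew] += 1.0;
    }
    if (it >= burn_in) {
      ++n_samples;
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta_acc[(size_t)d * K + k] +=
            (ndk[(size_t)d * K + k] + alpha) / (nd[d] + K * alpha);
      for (int m = 0; m < M; ++m) {
        const double bm = beta[m], Vm = (double)V[m];
        for (int k = 0; k < K; ++k)
          for (int w = 0; w < V[m]; ++w)
            phi_acc[m][(size_t)k * V[m] + w] +=
              (nkw[m][(size_t)k * V[m] + w] + bm) / (nk[m][k] + bm * Vm);
      }
    }
  }

  NumericMatrix theta(D, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k)
      theta(d, k) = theta_acc[(size_t)d * K + k] / n_samples;
  List phi(M);
  for (int m = 0; m < M; ++m) {
    NumericMatrix pm(K, V[m]);
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V[m]; ++w)
        pm(k, w) = phi_acc[m][(size_t)k * V[m] + w] / n_samples;
    phi[m] = pm;
  }
  return List::create(_["theta"] = theta, _["phi"] = phi);
}

// Fold a held-out document in: Gibbs over its tokens only, phi frozen.
// Returns the averaged topic proportions for the query document.
// [[Rcpp::export]]
NumericVector gibbs_fold_in_cpp(IntegerVector mod, IntegerVector word,
                                int K, List phi, double alpha,
                                int n_iter, int burn_in) {
  const int N = mod.size();
  std::vector<int> z(N);
  std::vector<double> nqk(K, 0.0);
  const int M = phi.size();
  std::vector<NumericMatrix> ph(M);
  for (int m = 0; m < M; ++m) ph[m] = as<NumericMatrix>(phi[m]);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    nqk[k] += 1.0;
  }

  std::vector<double> p(K), acc(K, 0.0);
  int n_samples = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int m = mod[i], w = word[i], kold = z[i];
      nqk[kold] -= 1.0;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (nqk[k] + alpha) * ph[m](k, w);
        total += p[k];
      }
      const int knew = sample_cat(p, K, total);
      z[i] = knew;
      nqk[knew] += 1.0;
    }
    if (it >= burn_in) {
      ++n_samples;
      for (int k = 0; k < K; ++k) acc[k] += (nqk[k] + alpha) / (N + K * alpha);
    }
  }
  NumericVector theta(K);
  for (int k = 0; k < K; ++k) theta[k] = acc[k] / n_samples;
  return theta;
}
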