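#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Topic assignments are resampled token by token from the collapsed
// conditional  p(z = k | .) ~ (n_dk + alpha) (n_kw + beta) / (n_k + V beta).
// theta and phi are reported as posterior means over thinned post-burn-in
// count snapshots with Dirichlet smoothing. Randomness comes from R's RNG
// (via unif_rand), so results are reproducible with set.seed().

static double joint_log_lik(const std::vector<int>& nkv,
                            const std::vector<int>& nk,
                            const std::vector<int>& ndk,
                            const std::vector<int>& nd,
                            int D, int K, int V,
                            double alpha, double beta) {
  double ll = K * (R::lgammafn(V * beta) - V * R::lgammafn(beta));
  for (int k = 0; k < K; ++k) {
    for (int v = 0; v < V; ++v) ll += R::lgammafn(nkv[k * V + v] + beta);
    ll -= R::lgammafn(nk[k] + V * beta);
  }
  ll += D * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
  for (int d = 0; d < D; ++d) {
    for (int k = 0; k < K; ++k) ll += R::lgammafn(ndk[d * K + k] + alpha);
    ll -= R::lgammafn(nd[d] + K * alpha);
  }
  return ll;
}

// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int K, int V, double alpha, double beta,
                   int n_iter, int burn_in, int thin) {
  int D = docs.size();
  std::vector<std::vector<int> > w(D);
  int total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    for (size_t i = 0; i < w[d].size(); ++i) {
      w[d][i] -= 1;  // to 0-based
      if (w[d][i] < 0 || w[d][i] >= V) stop("word index out of range");
    }
    total_tokens += w[d].size();
  }
  if (total_tokens == 0) stop("degenerate document-term data: no tokens");

  std::vector<int> nkv(K * V, 0), nk(K, 0), ndk(D * K, 0), nd(D, 0);
  std::vector<std::vector<int> > z(D);

  // init: uniform random topics
  for (int d = 0; d < D; ++d) {
    z[d].resize(w[d].size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ++nkv[k * V + w[d][i]];
      ++nk[k];
      ++ndk[d * K + k];
      ++nd[d];
    }
  }

  std::vector<double> phi_sum(K * V, 0.0), theta_sum(D * K, 0.0);
  std::vector<double> prob(K);
  NumericVector trace(n_iter);
  int n_snap = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        int word = w[d][i];
        int old = z[d][i];
        --nkv[old * V + word];
        --nk[old];
        --ndk[d * K + old];
        double cum = 0.0;
        for (int k = 0; k < K; ++k) {
          cum += (ndk[d * K + k] + alpha) * (nkv[k * V + word] + beta) /
                 (nk[k] + V * beta);
          prob[k] = cum;
        }
        double u = unif_rand() * cum;
        int knew = 0;
        while (knew < K - 1 && prob[knew] < u) ++knew;
        z[d][i] = knew;
        ++nkv[knew * V + word];
        ++nk[knew];
        ++ndk[d * K + knew];
      }
    }
    trace[iter] = joint_log_lik(nkv, nk, ndk, nd, D, K, V, alpha, beta);
    if (iter >= burn_in && ((iter - burn_in) % thin) == 0) {
      ++n_snap;
      for (int k = 0; k < K; ++k) {
        double denom = nk[k] + V * beta;
        for (int v = 0; v < V; ++v)
          phi_sum[k * V + v] += (nkv[k * V + v] + beta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        double denom = nd[d] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_sum[d * K + k] += (ndk[d * K + k] + alpha) / denom;
      }
    }
  }
  if (n_snap == 0) stop("no post-burn-in snapshots; lower burn_in or thin");

  NumericMatrix phi(K, V), theta(D, K);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi(k, v) = phi_sum[k * V + v] / n_snap;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = theta_sum[d * K + k] / n_snap;
  // exact renormalization (snapshot averages are already stochastic rows)
  for (int k = 0; k < K; ++k) {
    double s = 0; for (int v = 0; v < V; ++v) s += phi(k, v);
    for (int v = 0; v < V; ++v) phi(k, v) /= s;
  }
  for (int d = 0; d < D; ++d) {
    double s = 0; for (int k = 0; k < K; ++k) s += theta(d, k);
    for (int k = 0; k < K; ++k) theta(d, k) /= s;
  }
  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["log_likelihood"] = trace,
                      _["n_snapshots"] = n_snap);
}
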