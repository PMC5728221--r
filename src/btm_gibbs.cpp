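#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the Biterm Topic Model.
//
// State: z[b] in 0..K-1 per biterm, with sufficient statistics
//   nk[k]    = number of biterms assigned to topic k
//   nwk[w,k] = number of word slots of word w assigned to topic k
// Conditional with biterm b=(w1,w2) removed from the counts:
//   P(z_b=k | ...) propto (nk[k]+alpha) * (nwk[w1,k]+beta)*(nwk[w2,k]+beta)
//                         / ((2*nk[k]+M*beta) * (2*nk[k]+1+M*beta))
// All randomness comes from R's RNG stream (unif_rand), so results are
// reproducible under set.seed().

static inline int sample_topic(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int K = (int)w.size();
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Corpus log-likelihood under point estimates computed from current counts:
// sum_b log sum_k theta_k * phi_{k,w1} * phi_{k,w2}
static double corpus_loglik(const IntegerMatrix& biterms,
                            const std::vector<double>& nk,
                            const std::vector<double>& nwk,
                            int M, int K, double alpha, double beta) {
  int B = biterms.nrow();
  std::vector<double> theta(K), denom(K);
  for (int k = 0; k < K; ++k) {
    theta[k] = (nk[k] + alpha) / (B + K * alpha);
    denom[k] = 2.0 * nk[k] + M * beta;
  }
  double ll = 0.0;
  for (int b = 0; b < B; ++b) {
    int w1 = biterms(b, 0), w2 = biterms(b, 1);
    double pb = 0.0;
    for (int k = 0; k < K; ++k) {
      double p1 = (nwk[w1 * K + k] + beta) / denom[k];
      double p2 = (nwk[w2 * K + k] + beta) / denom[k];
      pb += theta[k] * p1 * p2;
    }
    ll += std::log(pb);
  }
  return ll;
}

// [[Rcpp::export]]
List btm_gibbs_cpp(IntegerMatrix biterms, int M, int K,
                   double alpha, double beta,
                   int n_sweeps, int burn_in,
                   IntegerVector z_init,
                   bool track_assign, bool track_loglik) {
  int B = biterms.nrow();
  if (B == 0) stop("no biterms");
  std::vector<int> z(z_init.begin(), z_init.end());
  std::vector<double> nk(K, 0.0), nwk((size_t)M * K, 0.0);
  for (int b = 0; b < B; ++b) {
    int k = z[b];
    nk[k] += 1.0;
    nwk[biterms(b, 0) * K + k] += 1.0;
    nwk[biterms(b, 1) * K + k] += 1.0;
  }

  std::vector<double> nk_sum(K, 0.0), nwk_sum((size_t)M * K, 0.0);
  NumericMatrix assign_counts(track_assign ? B : 1, K);
  NumericVector loglik(track_loglik ? n_sweeps : 0);
  int n_kept = 0;
  std::vector<double> w(K);

  for (int s = 0; s < n_sweeps; ++s) {
    for (int b = 0; b < B; ++b) {
      int w1 = biterms(b, 0), w2 = biterms(b, 1);
      int old = z[b];
      nk[old] -= 1.0;
      nwk[w1 * K + old] -= 1.0;
      nwk[w2 * K + old] -= 1.0;
      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = 2.0 * nk[k] + M * beta;
        double wk = (nk[k] + alpha)
          * (nwk[w1 * K + k] + beta) * (nwk[w2 * K + k] + beta)
          / (d * (d + 1.0));
        w[k] = wk;
        total += wk;
      }
      int knew = sample_topic(w, total);
      z[b] = knew;
      nk[knew] += 1.0;
      nwk[w1 * K + knew] += 1.0;
      nwk[w2 * K + knew] += 1.0;
    }
    if (track_loglik) {
      loglik[s] = corpus_loglik(biterms, nk, nwk, M, K, alpha, beta);
    }
    if (s >= burn_in) {
      ++n_kept;
      for (int k = 0; k < K; ++k) nk_sum[k] += nk[k];
      for (size_t i = 0; i < nwk.size(); ++i) nwk_sum[i] += nwk[i];
      if (track_assign) {
        for (int b = 0; b < B; ++b) assign_counts(b, z[b]) += 1.0;
      }
    }
  }

  NumericVector nk_out(K), nk_mean(K);
  NumericMatrix nwk_out(M, K), nwk_mean(M, K);
  for (int k = 0; k < K; ++k) {
    nk_out[k] = nk[k];
    nk_mean[k] = n_kept > 0 ? nk_sum[k] / n_kept : nk[k];
    for (int m = 0; m < M; ++m) {
      nwk_out(m, k) = nwk[m * K + k];
      nwk_mean(m, k) = n_kept > 0 ? nwk_sum[(size_t)m * K + k] / n_kept
                                  : nwk[m * K + k];
    }
  }
  if (track_assign && n_kept > 0) {
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < K; ++k) assign_counts(b, k) /= n_kept;
  }

  return List::create(
    _["z"] = IntegerVector(z.begin(), z.end()),
    _["n_k"] = nk_out,
    _["n_wk"] = nwk_out,
    _["n_k_mean"] = nk_mean,
    _["n_wk_mean"] = nwk_mean,
    _["loglik"] = loglik,
    _["assign_freq"] = track_assign ? assign_counts : NumericMatrix(0, 0),
    _["n_kept"] = n_kept
  );
}
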