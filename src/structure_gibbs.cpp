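#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for model-based clustering of multilocus diploid
// genotypes with an uncorrelated allele-frequency prior
// Dirichlet(lambda).  Sweeps alternate: allele frequencies P | Z,
// copy origins Z | P,Q, and memberships Q | Z (admixture model, with a
// Metropolis step on the common Dirichlet parameter alpha) or hard
// cluster assignments (no-admixture model).  Uses R's RNG so results
// are reproducible under set.seed().

static double rgamma_pos(double shape) {
  double x = R::rgamma(shape, 1.0);
  return (x > 0.0) ? x : 1e-300;
}

// [[Rcpp::export(name = ".structure_gibbs")]]
List structure_gibbs(IntegerMatrix a1, IntegerMatrix a2,
                     IntegerVector n_alleles, int K, bool admixture,
                     int burnin, int iters, double lambda,
                     double alpha_init, double alpha_step,
                     double alpha_max, int thin) {
  const int N = a1.nrow(), L = a1.ncol();
  int maxA = 0;
  for (int l = 0; l < L; ++l) maxA = std::max(maxA, (int)n_alleles[l]);

  std::vector<int> z1(N * L, -1), z2(N * L, -1);
  std::vector<double> P((size_t)K * L * maxA, 0.0);
  std::vector<int> counts((size_t)K * L * maxA, 0);
  std::vector<int> m((size_t)N * K, 0);          // copies of i in k
  NumericMatrix q(N, K);
  NumericMatrix qsum(N, K);
  std::vector<double> lnl_all(burnin + iters);
  std::vector<double> alpha_trace;
  std::vector<double> lnl_trace;
  double alpha = alpha_init;
  int alpha_accept = 0, alpha_tries = 0;

  auto Pidx = [&](int k, int l, int a) {
    return ((size_t)k * L + l) * maxA + a;
  };

  // init: random origins, uniform q
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
    for (int l = 0; l < L; ++l) {
      if (a1(i, l) < 0) continue;
      int k1 = (int)(R::unif_rand() * K); if (k1 == K) k1 = K - 1;
      int k2 = (int)(R::unif_rand() * K); if (k2 == K) k2 = K - 1;
      z1[i * L + l] = k1; z2[i * L + l] = k2;
      counts[Pidx(k1, l, a1(i, l))]++;
      counts[Pidx(k2, l, a2(i, l))]++;
      m[i * K + k1]++; m[i * K + k2]++;
    }
  }

  std::vector<double> prob(K), loglik(K);
  const int total = burnin + iters;
  for (int sweep = 0; sweep < total; ++sweep) {
    // P | Z : Dirichlet(lambda + counts)
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = rgamma_pos(lambda + counts[Pidx(k, l, a)]);
          P[Pidx(k, l, a)] = g;
          s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a) P[Pidx(k, l, a)] /= s;
      }
    }

    if (admixture || K == 1) {
      // Z | P, Q per allele copy
      std::fill(counts.begin(), counts.end(), 0);
      std::fill(m.begin(), m.end(), 0);
      for (int i = 0; i < N; ++i) {
        for (int l = 0; l < L; ++l) {
          if (a1(i, l) < 0) continue;
          for (int c = 0; c < 2; ++c) {
            int a = (c == 0) ? a1(i, l) : a2(i, l);
            double s = 0.0;
            for (int k = 0; k < K; ++k) {
              prob[k] = q(i, k) * P[Pidx(k, l, a)];
              s += prob[k];
            }
            double u = R::unif_rand() * s, cum = 0.0;
            int zk = K - 1;
            for (int k = 0; k < K; ++k) {
              cum += prob[k];
              if (u <= cum) { zk = k; break; }
            }
            if (c == 0) z1[i * L + l] = zk; else z2[i * L + l] = zk;
            counts[Pidx(zk, l, a)]++;
            m[i * K + zk]++;
          }
        }
      }
      // Q | Z : Dirichlet(alpha + m_i)
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = rgamma_pos(alpha + m[i * K + k]);
          q(i, k) = g; s += g;
        }
        for (int k = 0; k < K; ++k) q(i, k) /= s;
      }
      // alpha | Q : random-walk Metropolis, uniform(0, alpha_max) prior
      if (admixture && K > 1) {
        double slogq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) slogq += std::log(q(i, k));
        double prop = alpha + R::norm_rand() * alpha_step;
        while (prop < 0.0 || prop > alpha_max) {
          if (prop < 0.0) prop = -prop;
          if (prop > alpha_max) prop = 2.0 * alpha_max - prop;
        }
        if (prop > 0.0) {
          double lr = N * (std::lgamma(K * prop) - K * std::lgamma(prop))
                    - N * (std::lgamma(K * alpha) - K * std::lgamma(alpha))
                    + (prop - alpha) * slogq;
          ++alpha_tries;
          if (std::log(R::unif_rand()) < lr) { alpha = prop; ++alpha_accept; }
        }
      }
    } else {
      // no-admixture: one origin per individual
      std::fill(counts.begin(), counts.end(), 0);
      std::fill(m.begin(), m.end(), 0);
      for (int i = 0; i < N; ++i) {
        double best = -1e300;
        for (int k = 0; k < K; ++k) {
          double ll = 0.0;
          for (int l = 0; l < L; ++l) {
            if (a1(i, l) < 0) continue;
            ll += std::log(P[Pidx(k, l, a1(i, l))]);
            ll += std::log(P[Pidx(k, l, a2(i, l))]);
          }
          loglik[k] = ll;
          if (ll > best) best = ll;
        }
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[k] = std::exp(loglik[k] - best);
          s += prob[k];
        }
        double u = R::unif_rand() * s, cum = 0.0;
        int zi = K - 1;
        for (int k = 0; k < K; ++k) {
          cum += prob[k];
          if (u <= cum) { zi = k; break; }
        }
        for (int k = 0; k < K; ++k) q(i, k) = (k == zi) ? 1.0 : 0.0;
        for (int l = 0; l < L; ++l) {
          if (a1(i, l) < 0) continue;
          z1[i * L + l] = zi; z2[i * L + l] = zi;
          counts[Pidx(zi, l, a1(i, l))]++;
          counts[Pidx(zi, l, a2(i, l))]++;
          m[i * K + zi] += 2;
        }
      }
    }

    // log-likelihood of the data given (P, Q)
    double lnl = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        if (a1(i, l) < 0) continue;
        for (int c = 0; c < 2; ++c) {
          int a = (c == 0) ? a1(i, l) : a2(i, l);
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += q(i, k) * P[Pidx(k, l, a)];
          lnl += std::log(s);
        }
      }
    }
    lnl_all[sweep] = lnl;
    if (sweep % thin == 0) {
      lnl_trace.push_back(lnl);
      if (admixture) alpha_trace.push_back(alpha);
    }
    if (sweep >= burnin) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += q(i, k);
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) qsum(i, k) /= iters;

  NumericVector lnl_post(iters);
  for (int s = 0; s < iters; ++s) lnl_post[s] = lnl_all[burnin + s];

  return List::create(
    _["q"] = qsum,
    _["lnl_post"] = lnl_post,
    _["lnl_trace"] = NumericVector(lnl_trace.begin(), lnl_trace.end()),
    _["alpha_trace"] = NumericVector(alpha_trace.begin(),
                                     alpha_trace.end()),
    _["alpha_accept_rate"] =
      alpha_tries > 0 ? (double)alpha_accept / alpha_tries : NA_REAL);
}
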