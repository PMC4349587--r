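// Bayesian admixture model with independent allele frequencies: Gibbs
// sampler over latent per-gene-copy origin indicators Z, cluster allele
// frequencies P (Dirichlet(lambda) prior, independent across clusters),
// per-individual admixture proportions Q (symmetric Dirichlet(alpha)), and
// a scalar alpha with uniform(0, alpha_max] prior updated by a
// random-walk Metropolis step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

void rdirichlet_into(double* out, const double* alpha, int m) {
  double s = 0.0;
  for (int a = 0; a < m; ++a) {
    double g = R::rgamma(alpha[a], 1.0);
    if (g < 1e-300) g = 1e-300;
    out[a] = g;
    s += g;
  }
  for (int a = 0; a < m; ++a) out[a] /= s;
}

int sample_cat(const double* w, int m) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) s += w[k];
  double u = R::unif_rand() * s;
  double acc = 0.0;
  for (int k = 0; k < m; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return m - 1;
}

}  // namespace

// g1, g2: n x L allele-index matrices (0-based; -1 = missing)
// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix g1, IntegerMatrix g2,
                         IntegerVector n_alleles, int K,
                         int burnin, int sweeps,
                         double lambda, double alpha_init,
                         double alpha_max, double alpha_sd) {
  const int n = g1.nrow(), L = g1.ncol();
  RNGScope scope;

  // cluster allele frequencies P[k][l] (length n_alleles[l])
  std::vector<std::vector<std::vector<double>>> P(K);
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l].resize(n_alleles[l]);
      std::vector<double> pr(n_alleles[l], lambda);
      rdirichlet_into(P[k][l].data(), pr.data(), n_alleles[l]);
    }
  }
  std::vector<std::vector<double>> q(n, std::vector<double>(K));
  {
    std::vector<double> ones(K, 1.0);
    for (int i = 0; i < n; ++i) rdirichlet_into(q[i].data(), ones.data(), K);
  }
  // latent origins per gene copy
  std::vector<std::vector<int>> z1(n, std::vector<int>(L, 0));
  std::vector<std::vector<int>> z2(n, std::vector<int>(L, 0));
  double alpha = alpha_init;

  std::vector<std::vector<double>> qsum(n, std::vector<double>(K, 0.0));
  NumericVector lnL_trace(sweeps);
  double alpha_sum = 0.0;
  std::vector<double> w(K);

  // scratch: per-cluster allele counts
  std::vector<std::vector<std::vector<double>>> cnt(K);
  for (int k = 0; k < K; ++k) {
    cnt[k].resize(L);
    for (int l = 0; l < L; ++l) cnt[k][l].resize(n_alleles[l]);
  }

  const int total = burnin + sweeps;
  for (int it = 0; it < total; ++it) {
    // Z updates
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l) {
        int a1 = g1(i, l), a2 = g2(i, l);
        if (a1 < 0) continue;
        for (int k = 0; k < K; ++k) w[k] = q[i][k] * P[k][l][a1];
        z1[i][l] = sample_cat(w.data(), K);
        for (int k = 0; k < K; ++k) w[k] = q[i][k] * P[k][l][a2];
        z2[i][l] = sample_cat(w.data(), K);
      }
    // P updates
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(cnt[k][l].begin(), cnt[k][l].end(), lambda);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l) {
        int a1 = g1(i, l), a2 = g2(i, l);
        if (a1 < 0) continue;
        cnt[z1[i][l]][l][a1] += 1.0;
        cnt[z2[i][l]][l][a2] += 1.0;
      }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        rdirichlet_into(P[k][l].data(), cnt[k][l].data(), n_alleles[l]);
    // Q updates
    std::vector<double> dpar(K);
    for (int i = 0; i < n; ++i) {
      std::fill(dpar.begin(), dpar.end(), alpha);
      for (int l = 0; l < L; ++l) {
        if (g1(i, l) < 0) continue;
        dpar[z1[i][l]] += 1.0;
        dpar[z2[i][l]] += 1.0;
      }
      rdirichlet_into(q[i].data(), dpar.data(), K);
    }
    // alpha Metropolis (only meaningful for K > 1)
    if (K > 1) {
      double prop = alpha + R::norm_rand() * alpha_sd;
      if (prop > 0.0 && prop <= alpha_max) {
        double sumlogq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            sumlogq += std::log(std::max(q[i][k], 1e-300));
        double logr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                         - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                    + (prop - alpha) * sumlogq;
        if (std::log(R::unif_rand()) < logr) alpha = prop;
      }
    }
    // complete-data log-likelihood of observed copies given (Q, P)
    if (it >= burnin) {
      double lnL = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l) {
          int a1 = g1(i, l), a2 = g2(i, l);
          if (a1 < 0) continue;
          double m1 = 0.0, m2 = 0.0;
          for (int k = 0; k < K; ++k) {
            m1 += q[i][k] * P[k][l][a1];
            m2 += q[i][k] * P[k][l][a2];
          }
          lnL += std::log(std::max(m1, 1e-300)) + std::log(std::max(m2, 1e-300));
        }
      lnL_trace[it - burnin] = lnL;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum[i][k] += q[i][k];
      alpha_sum += alpha;
    }
  }

  NumericMatrix qmean(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += qsum[i][k];
    for (int k = 0; k < K; ++k) qmean(i, k) = qsum[i][k] / s;
  }
  return List::create(_["q"] = qmean, _["lnL"] = lnL_trace,
                      _["alpha"] = alpha_sum / sweeps);
}
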