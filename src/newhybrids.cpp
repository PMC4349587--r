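// Six-category genealogical-class mixture model: Gibbs sampler over latent
// class indicators z_i in {P1, P2, F1, F2, BC1, BC2}, latent per-gene-copy
// pool origins, the two parental pool allele-frequency vectors (Dirichlet
// prior: Jeffreys-like 1/A_l per allele, or uniform 1), and class mixing
// proportions pi (uniform Dirichlet prior). Each class is characterized by
// its genotype frequency class (GFC): the Mendelian probabilities that a
// diploid locus carries 2, 1 or 0 gene copies from pool A.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int NCLASS = 6;
// rows: P1, P2, F1, F2, BC1, BC2; cols: phi_AA, phi_het, phi_BB
const double GFC[NCLASS][3] = {
  {1.0, 0.0, 0.0},
  {0.0, 0.0, 1.0},
  {0.0, 1.0, 0.0},
  {0.25, 0.5, 0.25},
  {0.5, 0.5, 0.0},
  {0.0, 0.5, 0.5}
};

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

// genotype probability under one class at one locus
double geno_lik(int a1, int a2, const double* phi,
                const std::vector<double>& pA, const std::vector<double>& pB) {
  if (a1 == a2) {
    return phi[0] * pA[a1] * pA[a1] + phi[1] * pA[a1] * pB[a1]
         + phi[2] * pB[a1] * pB[a1];
  }
  return phi[0] * 2.0 * pA[a1] * pA[a2]
       + phi[1] * (pA[a1] * pB[a2] + pA[a2] * pB[a1])
       + phi[2] * 2.0 * pB[a1] * pB[a2];
}

}  // namespace

// [[Rcpp::export(name = ".newhybrids_gibbs_cpp")]]
List newhybrids_gibbs_cpp(IntegerMatrix g1, IntegerMatrix g2,
                          IntegerVector n_alleles,
                          int burnin, int sweeps, bool jeffreys) {
  const int n = g1.nrow(), L = g1.ncol();
  RNGScope scope;

  std::vector<std::vector<double>> pA(L), pB(L), priorv(L);
  for (int l = 0; l < L; ++l) {
    int A = n_alleles[l];
    priorv[l].assign(A, jeffreys ? 1.0 / A : 1.0);
    pA[l].resize(A);
    pB[l].resize(A);
    // initialize pools from the prior perturbed by overall counts
    std::vector<double> cnts(priorv[l]);
    for (int i = 0; i < n; ++i) {
      if (g1(i, l) < 0) continue;
      cnts[g1(i, l)] += 0.5;
      cnts[g2(i, l)] += 0.5;
    }
    rdirichlet_into(pA[l].data(), cnts.data(), A);
    rdirichlet_into(pB[l].data(), cnts.data(), A);
  }
  std::vector<int> z(n);
  for (int i = 0; i < n; ++i) z[i] = (int)(R::unif_rand() * NCLASS) % NCLASS;
  std::vector<double> pi(NCLASS, 1.0 / NCLASS);

  std::vector<std::vector<double>> post(n, std::vector<double>(NCLASS, 0.0));
  NumericVector lnL_trace(sweeps);
  std::vector<std::vector<double>> cntA(L), cntB(L);
  for (int l = 0; l < L; ++l) {
    cntA[l].resize(n_alleles[l]);
    cntB[l].resize(n_alleles[l]);
  }

  double wcls[NCLASS], wcfg[8];
  const int total = burnin + sweeps;
  for (int it = 0; it < total; ++it) {
    // class indicators
    double lnL = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < NCLASS; ++c) {
        double lik = pi[c];
        for (int l = 0; l < L; ++l) {
          int a1 = g1(i, l), a2 = g2(i, l);
          if (a1 < 0) continue;
          lik *= geno_lik(a1, a2, GFC[c], pA[l], pB[l]);
        }
        wcls[c] = lik;
      }
      z[i] = sample_cat(wcls, NCLASS);
      if (it >= burnin) {
        double s = 0.0;
        for (int c = 0; c < NCLASS; ++c) s += wcls[c];
        lnL += std::log(std::max(s, 1e-300));
      }
    }
    // latent origins -> pool allele counts; configurations are ordered
    // origin pairs x allele-to-copy pairings
    for (int l = 0; l < L; ++l) {
      std::copy(priorv[l].begin(), priorv[l].end(), cntA[l].begin());
      std::copy(priorv[l].begin(), priorv[l].end(), cntB[l].begin());
    }
    for (int i = 0; i < n; ++i) {
      const double* phi = GFC[z[i]];
      // ordered-origin weights: AA, AB, BA, BB
      const double ow[4] = {phi[0], phi[1] / 2.0, phi[1] / 2.0, phi[2]};
      for (int l = 0; l < L; ++l) {
        int a1 = g1(i, l), a2 = g2(i, l);
        if (a1 < 0) continue;
        int ncfg = 0;
        int cfg_o[8][2], cfg_a[8][2];
        const int npair = (a1 == a2) ? 1 : 2;
        for (int o = 0; o < 4; ++o) {
          int o1 = o >> 1, o2 = o & 1;  // 0 = A, 1 = B
          for (int pr = 0; pr < npair; ++pr) {
            int x = pr == 0 ? a1 : a2;
            int y = pr == 0 ? a2 : a1;
            double px = o1 == 0 ? pA[l][x] : pB[l][x];
            double py = o2 == 0 ? pA[l][y] : pB[l][y];
            wcfg[ncfg] = ow[o] * px * py;
            cfg_o[ncfg][0] = o1; cfg_o[ncfg][1] = o2;
            cfg_a[ncfg][0] = x;  cfg_a[ncfg][1] = y;
            ++ncfg;
          }
        }
        int pick = sample_cat(wcfg, ncfg);
        for (int s = 0; s < 2; ++s) {
          if (cfg_o[pick][s] == 0) cntA[l][cfg_a[pick][s]] += 1.0;
          else                     cntB[l][cfg_a[pick][s]] += 1.0;
        }
      }
    }
    for (int l = 0; l < L; ++l) {
      rdirichlet_into(pA[l].data(), cntA[l].data(), n_alleles[l]);
      rdirichlet_into(pB[l].data(), cntB[l].data(), n_alleles[l]);
    }
    // mixing proportions
    {
      double dpar[NCLASS];
      for (int c = 0; c < NCLASS; ++c) dpar[c] = 1.0;
      for (int i = 0; i < n; ++i) dpar[z[i]] += 1.0;
      rdirichlet_into(pi.data(), dpar, NCLASS);
    }
    if (it >= burnin) {
      lnL_trace[it - burnin] = lnL;
      for (int i = 0; i < n; ++i) post[i][z[i]] += 1.0;
    }
  }

  NumericMatrix pm(n, NCLASS);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NCLASS; ++c) pm(i, c) = post[i][c] / sweeps;
  return List::create(_["posterior"] = pm, _["lnL"] = lnL_trace);
}
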