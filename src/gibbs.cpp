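#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// No-admixture, uncorrelated-frequency Gibbs sampler for K population
// clusters. Genotypes are passed as two parallel matrices of 0-based allele
// indices per locus (-1 = missing). Alternates (a) Dirichlet(1 + counts)
// draws of cluster allele frequencies given labels and (b) label draws from
// each individual's full conditional. Records the data log-likelihood
// (heterozygote factor 2 included) each sweep and per-individual label
// counts after burn-in. Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export]]
List cpp_gibbs_cluster(IntegerMatrix a1, IntegerMatrix a2,
                       IntegerVector nAlleles, int K,
                       int burnin, int iters) {
  int n = a1.nrow(), L = a1.ncol();
  RNGScope scope;
  std::vector<NumericMatrix> logp(L);
  for (int l = 0; l < L; l++) logp[l] = NumericMatrix(K, nAlleles[l]);
  std::vector<int> z(n);
  for (int i = 0; i < n; i++) z[i] = (int)(unif_rand() * K);
  IntegerMatrix zcount(n, K);
  NumericVector trace(burnin + iters);
  std::vector<double> lp(K), pr(K);

  for (int sweep = 0; sweep < burnin + iters; sweep++) {
    for (int l = 0; l < L; l++) {
      int A = nAlleles[l];
      std::vector<double> cnt((size_t)K * A, 1.0); // Dirichlet prior 1 per allele
      for (int i = 0; i < n; i++) {
        if (a1(i, l) < 0) continue;
        cnt[(size_t)z[i] * A + a1(i, l)] += 1.0;
        cnt[(size_t)z[i] * A + a2(i, l)] += 1.0;
      }
      for (int k = 0; k < K; k++) {
        double s = 0.0;
        std::vector<double> g(A);
        for (int a = 0; a < A; a++) {
          g[a] = R::rgamma(cnt[(size_t)k * A + a], 1.0);
          if (g[a] < 1e-300) g[a] = 1e-300;
          s += g[a];
        }
        for (int a = 0; a < A; a++) logp[l](k, a) = std::log(g[a] / s);
      }
    }
    double ll = 0.0;
    for (int i = 0; i < n; i++) {
      for (int k = 0; k < K; k++) lp[k] = 0.0;
      double lhet = 0.0;
      for (int l = 0; l < L; l++) {
        int x = a1(i, l);
        if (x < 0) continue;
        int y = a2(i, l);
        if (x != y) lhet += M_LN2;
        for (int k = 0; k < K; k++) lp[k] += logp[l](k, x) + logp[l](k, y);
      }
      double mx = lp[0];
      for (int k = 1; k < K; k++) if (lp[k] > mx) mx = lp[k];
      double tot = 0.0;
      for (int k = 0; k < K; k++) { pr[k] = std::exp(lp[k] - mx); tot += pr[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int znew = K - 1;
      for (int k = 0; k < K; k++) { acc += pr[k]; if (u <= acc) { znew = k; break; } }
      z[i] = znew;
      ll += lp[znew] + lhet;
      if (sweep >= burnin) zcount(i, znew) += 1;
    }
    trace[sweep] = ll;
  }
  return List::create(_["zcount"] = zcount, _["trace"] = trace);
}
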