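#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// Coalescent simulation of a microsatellite sample at mutation-drift
// equilibrium under the two-phase mutation model (TPM). A Kingman genealogy
// of n gene copies is simulated backward in time; mutations arrive on
// active lineages at rate theta/2 per lineage and shift the repeat count of
// every descendant leaf by a signed step (magnitude 1 with probability
// 1 - pMultistep, otherwise 2 + Geometric(q)). Step signs are symmetric, so
// backward application is distributionally identical to forward. Returns
// the observed allele count k and unbiased gene diversity H per replicate.

// [[Rcpp::export]]
List cpp_tpm_coalescent(int n, double theta, double pMultistep, double q,
                        int nReps) {
  RNGScope scope;
  IntegerVector kOut(nReps);
  NumericVector hOut(nReps);
  std::vector<int> state(n);

  for (int rep = 0; rep < nReps; rep++) {
    std::fill(state.begin(), state.end(), 0);
    std::vector< std::vector<int> > lin(n);
    for (int i = 0; i < n; i++) { lin[i].assign(1, i); }
    int a = n;
    while (a > 1) {
      double rateC = a * (a - 1) / 2.0;
      double t = R::rexp(1.0 / rateC);
      int nm = (int) R::rpois(a * theta / 2.0 * t);
      for (int m = 0; m < nm; m++) {
        int li = (int)(unif_rand() * a);
        int mag = 1;
        if (unif_rand() < pMultistep) mag = 2 + (int) R::rgeom(q);
        int step = (unif_rand() < 0.5) ? -mag : mag;
        for (size_t u = 0; u < lin[li].size(); u++) state[lin[li][u]] += step;
      }
      int i = (int)(unif_rand() * a);
      int j = (int)(unif_rand() * (a - 1));
      if (j >= i) j++;
      lin[i].insert(lin[i].end(), lin[j].begin(), lin[j].end());
      lin[j] = lin[a - 1];
      lin.pop_back();
      a--;
    }
    std::map<int, int> tab;
    for (int i = 0; i < n; i++) tab[state[i]]++;
    double sump2 = 0.0;
    for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it) {
      double p = (double)it->second / n;
      sump2 += p * p;
    }
    kOut[rep] = (int)tab.size();
    hOut[rep] = ((double)n / (n - 1)) * (1.0 - sump2);
  }
  return List::create(_["k"] = kOut, _["H"] = hOut);
}
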