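#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo null for the multinomial goodness-of-fit statistic against a
// fixed ambient profile. For a barcode with total t the statistic is
//   S = sum_g x_g log x_g - sum_g x_g log p_g - t log t
// (monotone in the likelihood-ratio deviance). Each iteration draws one
// long multinomial trajectory gene-by-gene and evaluates S incrementally at
// every requested total, so all barcodes share one stream of draws.
//
// `totals` must be sorted ascending; `stat_obs` aligned with it. Returns
// the add-one Monte-Carlo p-value (1 + #exceed) / (n_mc + 1) per barcode.
// [[Rcpp::export]]
NumericVector ambient_null_pvalues(NumericVector prob, IntegerVector totals,
                                   NumericVector stat_obs, int n_mc) {
  const int G = prob.size();
  const int B = totals.size();
  if (B == 0) return NumericVector(0);
  for (int i = 1; i < B; ++i)
    if (totals[i] < totals[i - 1]) stop("totals must be sorted ascending");

  std::vector<double> cum(G), logp(G);
  double s = 0.0;
  for (int g = 0; g < G; ++g) s += prob[g];
  double acc = 0.0;
  for (int g = 0; g < G; ++g) {
    acc += prob[g] / s;
    cum[g] = acc;
    logp[g] = std::log(prob[g] / s);
  }
  cum[G - 1] = 1.0;

  const int Tmax = totals[B - 1];
  std::vector<int> cnt(G, 0);
  std::vector<int> exceed(B, 0);

  for (int it = 0; it < n_mc; ++it) {
    std::fill(cnt.begin(), cnt.end(), 0);
    double A = 0.0, Bs = 0.0;
    int bi = 0;
    for (int t = 1; t <= Tmax; ++t) {
      double u = unif_rand();
      int g = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (g >= G) g = G - 1;
      int k = cnt[g]++;
      double kp1 = k + 1.0;
      A += kp1 * std::log(kp1) - (k > 0 ? k * std::log((double)k) : 0.0);
      Bs += logp[g];
      if (bi < B && totals[bi] == t) {
        double S = A - Bs - t * std::log((double)t);
        while (bi < B && totals[bi] == t) {
          if (S >= stat_obs[bi] - 1e-12) ++exceed[bi];
          ++bi;
        }
      }
    }
    if (it % 256 == 0) checkUserInterrupt();
  }

  NumericVector p(B);
  for (int i = 0; i < B; ++i)
    p[i] = (1.0 + exceed[i]) / (n_mc + 1.0);
  return p;
}
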