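#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear birth-death transition probabilities on states 0..nmax.
// Each ancestral copy leaves a geometric number of descendants:
// P(i->j) = sum_k C(i,k) p0^(i-k) (1-p0)^k C(j-1,k-1) (1-eta)^k eta^(j-k).
// Computed in log space with running binomial coefficients.
// [[Rcpp::export(name = ".bd_transition")]]
NumericMatrix bd_transition(double p0, double eta, int nmax) {
  NumericMatrix P(nmax + 1, nmax + 1);
  P(0, 0) = 1.0;
  const double lp0 = std::log(p0), l1p0 = std::log1p(-p0);
  const double leta = std::log(eta), l1eta = std::log1p(-eta);
  // lchoose tables
  std::vector<double> lg(2 * nmax + 2);
  lg[0] = 0.0;
  for (int i = 1; i < (int)lg.size(); ++i) lg[i] = lg[i - 1] + std::log(i);
  auto lchoose2 = [&](int n, int k) -> double {
    if (k < 0 || k > n) return R_NegInf;
    return lg[n] - lg[k] - lg[n - k];
  };
  for (int i = 1; i <= nmax; ++i) {
    P(i, 0) = std::exp(i * lp0);
    for (int j = 1; j <= nmax; ++j) {
      const int kmax = std::min(i, j);
      double acc = 0.0;
      for (int k = 1; k <= kmax; ++k) {
        const double lt = lchoose2(i, k) + (i - k) * lp0 + k * l1p0 +
                          lchoose2(j - 1, k - 1) + k * l1eta +
                          (j - k) * leta;
        acc += std::exp(lt);
      }
      P(i, j) = acc;
    }
  }
  return P;
}
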