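#include <Rcpp.h>
using namespace Rcpp;

// Orientationally averaged scattering intensity by the Debye double sum
// over point scatterers with uniform form factor f:
//   I(q) = f^2 * [ N + 2 * sum_{i<j} sin(q r_ij) / (q r_ij) ]
// dists holds the n*(n-1)/2 unique pair distances (as from stats::dist).
// [[Rcpp::export(name = ".debye_sum")]]
NumericVector debye_sum(NumericVector q, NumericVector dists, int n,
                        double f) {
  const R_xlen_t nq = q.size(), nd = dists.size();
  NumericVector I(nq);
  const double f2 = f * f;
  for (R_xlen_t k = 0; k < nq; ++k) {
    const double qk = q[k];
    double acc = 0.0;
    if (qk <= 0.0) {
      acc = (double)nd;  // sinc(0) = 1 for every pair
    } else {
      for (R_xlen_t m = 0; m < nd; ++m) {
        const double x = qk * dists[m];
        acc += (x < 1e-12) ? 1.0 : std::sin(x) / x;
      }
    }
    I[k] = f2 * ((double)n + 2.0 * acc);
  }
  return I;
}
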