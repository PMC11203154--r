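#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Single-site Metropolis over spin vectors s in {-1,+1}^L for the Gibbs
// weight exp(-lambda * (0.5 * s'Ws + c's)), W symmetric with arbitrary
// diagonal (the diagonal contributes a constant for spins and cancels in
// the flip rule). Random-scan sweeps; one sweep = L proposed flips.
//
// Returns an integer matrix of n_samples rows (states after burnin, spaced
// by thin sweeps). The RNG is a seeded mt19937 so streams are reproducible
// across platforms independently of R's RNG state.
// [[Rcpp::export]]
IntegerMatrix metropolis_sample_cpp(const NumericMatrix& W,
                                    const NumericVector& c,
                                    double lambda,
                                    int n_samples,
                                    int burnin_sweeps,
                                    int thin_sweeps,
                                    int seed,
                                    const IntegerVector& init) {
  const int L = c.size();
  if (W.nrow() != L || W.ncol() != L)
    stop("W must be L x L with L = length(c)");
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, L - 1);

  std::vector<double> s(L);
  for (int l = 0; l < L; ++l) s[l] = static_cast<double>(init[l]);

  // local field r_l = sum_{b != l} W[l,b] s_b + c_l, kept incrementally
  std::vector<double> r(L);
  for (int l = 0; l < L; ++l) {
    double acc = c[l];
    for (int b = 0; b < L; ++b) if (b != l) acc += W(l, b) * s[b];
    r[l] = acc;
  }

  IntegerMatrix out(n_samples, L);
  auto sweep = [&](void) {
    for (int t = 0; t < L; ++t) {
      int l = pick(rng);
      // action change for flipping site l: delta = -2 s_l r_l
      double delta = -2.0 * s[l] * r[l];
      if (delta <= 0.0 || unif(rng) < std::exp(-lambda * delta)) {
        double ds = -2.0 * s[l];
        s[l] = -s[l];
        for (int b = 0; b < L; ++b) if (b != l) r[b] += W(b, l) * ds;
      }
    }
  };

  for (int b = 0; b < burnin_sweeps; ++b) sweep();
  for (int n = 0; n < n_samples; ++n) {
    for (int t = 0; t < thin_sweeps; ++t) sweep();
    for (int l = 0; l < L; ++l) out(n, l) = static_cast<int>(s[l]);
  }
  return out;
}
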