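#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exposure-integrated dynamic speckle synthesis.
//
// Each pixel carries an independent complex circular-Gaussian field E(t) with
// field autocorrelation |g1(tau)| = exp(-tau/tau_c), realized as a first-order
// autoregressive process on a sub-step grid:
//   E_{k+1} = rho E_k + sqrt(1 - rho^2) w_k,   rho = exp(-dt/tau_c),
// with w_k standard complex Gaussian (variance 1/2 per quadrature, so
// E[|E|^2] = 1).  A frame intensity is the mean of |E|^2 over the sub-steps
// spanning the exposure; between frames the process is advanced by one exact
// AR jump over the inter-frame gap, so the field evolves continuously across
// the whole acquisition.  tau_c = Inf freezes the field (rho = 1).
//
// Uses R's RNG (state fetched/committed manually): results are reproducible
// bit-for-bit under set.seed().

// [[Rcpp::export(name = ".speckle_frames_cpp", rng = false)]]
NumericMatrix speckle_frames_cpp(NumericVector tau_c, int n_frames,
                                 double exposure, double interval,
                                 int substeps) {
  const int np = tau_c.size();
  if (n_frames < 1) stop("n_frames must be >= 1");
  if (substeps < 1) stop("substeps must be >= 1");
  if (exposure <= 0) stop("exposure must be positive");
  if (interval < exposure) stop("frame interval must be >= exposure");
  const double dt = exposure / substeps;
  const double gap = interval - exposure;

  for (int p = 0; p < np; ++p)
    if (!(tau_c[p] > 0))
      stop("tau_c must be positive (or Inf for a frozen field)");

  std::vector<double> er(np), ei(np), rho(np), sig(np), rho_g(np), sig_g(np);
  const double isq2 = std::sqrt(0.5);
  GetRNGstate();
  for (int p = 0; p < np; ++p) {
    const double tc = tau_c[p];
    const double r = std::isinf(tc) ? 1.0 : std::exp(-dt / tc);
    rho[p] = r;
    sig[p] = std::sqrt(std::max(0.0, 1.0 - r * r) * 0.5);
    const double rg = std::isinf(tc) ? 1.0 : std::exp(-gap / tc);
    rho_g[p] = rg;
    sig_g[p] = std::sqrt(std::max(0.0, 1.0 - rg * rg) * 0.5);
    er[p] = R::norm_rand() * isq2;
    ei[p] = R::norm_rand() * isq2;
  }

  NumericMatrix out(np, n_frames);
  for (int f = 0; f < n_frames; ++f) {
    for (int s = 0; s < substeps; ++s) {
      for (int p = 0; p < np; ++p) {
        er[p] = rho[p] * er[p] + sig[p] * R::norm_rand();
        ei[p] = rho[p] * ei[p] + sig[p] * R::norm_rand();
        out(p, f) += er[p] * er[p] + ei[p] * ei[p];
      }
    }
    for (int p = 0; p < np; ++p) out(p, f) /= substeps;
    if (gap > 0 && f < n_frames - 1) {
      for (int p = 0; p < np; ++p) {
        er[p] = rho_g[p] * er[p] + sig_g[p] * R::norm_rand();
        ei[p] = rho_g[p] * ei[p] + sig_g[p] * R::norm_rand();
      }
    }
  }
  PutRNGstate();
  return out;
}
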