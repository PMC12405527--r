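#include <Rcpp.h>
using namespace Rcpp;

// Compound-Poisson pmf by the Panjer recursion, returned on the log scale.
//
// The Luria-Delbrueck mutant-count distribution is compound Poisson: the
// number of mutation events per culture is Poisson(m) and each event
// contributes an observed colony count drawn from the per-event law r
// (r[k] = P(k colonies observed from one mutant clone), k = 0..nmax).
// Panjer: p0 = exp(-m (1 - r0)); p_n = (m / n) * sum_{k=1..n} k r_k p_{n-k}.
//
// The recursion is linear in p0, so it is run with p0 rescaled to 1 and the
// vector renormalized whenever it threatens to overflow; the accumulated
// log offset keeps the result exact for m of order 10^3 and beyond, where
// exp(-m) itself would underflow.
// [[Rcpp::export(name = ".panjer_logpmf")]]
NumericVector panjer_logpmf(double m, NumericVector r, int nmax) {
  if (nmax < 0) stop("nmax must be >= 0");
  if (r.size() < nmax + 1) stop("weight vector shorter than nmax + 1");
  NumericVector logp(nmax + 1);
  std::vector<double> p(nmax + 1, 0.0);
  double log_offset = -m * (1.0 - r[0]);  // true log p0
  p[0] = 1.0;
  const double BIG = 1e250;
  for (int n = 1; n <= nmax; ++n) {
    double s = 0.0;
    for (int k = 1; k <= n; ++k) s += k * r[k] * p[n - k];
    p[n] = m * s / n;
    if (p[n] > BIG) {
      for (int j = 0; j <= n; ++j) p[j] /= BIG;
      log_offset += std::log(BIG);
    }
  }
  for (int n = 0; n <= nmax; ++n)
    logp[n] = (p[n] > 0.0) ? std::log(p[n]) + log_offset : R_NegInf;
  return logp;
}

// Per-event observed-count law under partial plating.
//
// A mutant clone has final size j with probability q_j = 1/(j (j+1))
// (Lea-Coulson), and each of its j cells is recovered on the selective
// plate independently with probability eps. The observed count per event is
// therefore sum_j q_j Binomial(j, eps), accumulated here by iterating the
// Binomial(j, eps) pmf (truncated at nmax) over j via the one-step
// convolution b_{j+1} = (1-eps) b_j + eps shift(b_j).
//
// The iteration stops when the remaining clone-size tail can no longer move
// mass below nmax: sum_{i>j} q_i P(Bin(i,eps) <= nmax) <= P(Bin(j,eps) <=
// nmax) / (j+1), which is tracked through the truncated mass of b.
// [[Rcpp::export(name = ".thinned_clone_weights")]]
NumericVector thinned_clone_weights(double eps, int nmax, double tol = 1e-13) {
  if (eps <= 0.0 || eps > 1.0) stop("eps must be in (0, 1]");
  NumericVector r(nmax + 1);
  if (eps == 1.0) {
    for (int k = 1; k <= nmax; ++k) r[k] = 1.0 / ((double)k * (k + 1.0));
    return r;
  }
  std::vector<double> b(nmax + 1, 0.0);  // Binomial(j, eps) pmf on 0..nmax
  b[0] = 1.0;
  double ome = 1.0 - eps;
  double trunc_mass = 1.0;
  long j = 0;
  const long JMAX = 50000000L;
  while (j < JMAX) {
    // advance b from Binomial(j, eps) to Binomial(j + 1, eps)
    for (int k = nmax; k >= 1; --k) b[k] = ome * b[k] + eps * b[k - 1];
    b[0] *= ome;
    ++j;
    double qj = 1.0 / ((double)j * (j + 1.0));
    trunc_mass = 0.0;
    for (int k = 0; k <= nmax; ++k) {
      r[k] += qj * b[k];
      trunc_mass += b[k];
    }
    if (j > nmax && trunc_mass / (double)(j + 1) < tol) break;
  }
  return r;
}
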