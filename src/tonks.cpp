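#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a >= b) return a + log1p(std::exp(b - a));
  return b + log1p(std::exp(a - b));
}

// Grand-canonical partition function of hard rods of odd length a on a
// 1D lattice, carried in the log domain for stability at genome scale.
// logw[k-1] = mu - u(k) for dyad positions k (1-based); -Inf marks
// positions where no rod fits.
//
// Forward: F(i) = F(i-1) + w(i - h) * F(i - a), F(j) = 1 for j < a,
// where h = (a-1)/2, so i - h is the dyad of the rod ending at i.
// Backward is the mirror image. n(k) = w(k) F(k-h-1) B(k+h+1) / Z,
// Occ(i) = sum_{k=i-h}^{i+h} n(k), clipped at the lattice edges.
// [[Rcpp::export(name = ".tonks_recursion")]]
List tonks_recursion(NumericVector logw, int a) {
  const int L = logw.size();
  if (a % 2 == 0) stop("particle length a must be odd");
  const int h = (a - 1) / 2;
  NumericVector n(L), occ(L);
  if (L < a) {
    return List::create(_["logZ"] = 0.0, _["n"] = n, _["occ"] = occ);
  }
  for (int k = 0; k < L; ++k)
    if (!(R_finite(logw[k]) || logw[k] == R_NegInf))
      stop("non-finite statistical weight at position %d", k + 1);
  std::vector<double> logF(L + 1), logB(L + 2);
  for (int i = 0; i < a; ++i) logF[i] = 0.0;
  for (int i = a; i <= L; ++i) {
    const int k = i - h;  // 1-based dyad
    logF[i] = logaddexp(logF[i - 1], logw[k - 1] + logF[i - a]);
  }
  for (int i = L + 1; i >= L - a + 2; --i) logB[i] = 0.0;
  for (int i = L - a + 1; i >= 1; --i) {
    const int k = i + h;
    logB[i] = logaddexp(logB[i + 1], logw[k - 1] + logB[i + a]);
  }
  const double logZ = logF[L];
  for (int k = h + 1; k <= L - h; ++k) {
    const double v = logw[k - 1] + logF[k - h - 1] + logB[k + h + 1] - logZ;
    n[k - 1] = (v == R_NegInf) ? 0.0 : std::exp(v);
  }
  std::vector<double> cs(L + 1, 0.0);
  for (int i = 1; i <= L; ++i) cs[i] = cs[i - 1] + n[i - 1];
  for (int i = 1; i <= L; ++i) {
    const int lo = std::max(1, i - h), hi = std::min(L, i + h);
    occ[i - 1] = cs[hi] - cs[lo - 1];
  }
  return List::create(_["logZ"] = logZ, _["n"] = n, _["occ"] = occ);
}
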