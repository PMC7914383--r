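#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One IIR pass over all channels at once, direct form II transposed.
// X is channels x samples; the pass runs along time in direction dir
// (+1 forward, -1 backward) with zero initial state. Channels sit
// contiguously in each column, so the inner loop vectorizes.
static void iir_pass(std::vector<double>& x, int C, int n,
                     const std::vector<double>& b,
                     const std::vector<double>& a, int dir) {
  const int ns = (int)std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  std::copy(b.begin(), b.end(), bb.begin());
  std::copy(a.begin(), a.end(), aa.begin());
  std::vector<double> S((size_t)ns * C, 0.0);
  std::vector<double> y(C);
  const int t0 = dir > 0 ? 0 : n - 1;
  for (int k = 0; k < n; ++k) {
    const int t = t0 + dir * k;
    double* xt = &x[(size_t)t * C];
    for (int c = 0; c < C; ++c) y[c] = bb[0] * xt[c] + S[c];
    for (int i = 0; i < ns - 1; ++i) {
      double* Si = &S[(size_t)i * C];
      const double* Sn = &S[(size_t)(i + 1) * C];
      const double bi = bb[i + 1], ai = aa[i + 1];
      for (int c = 0; c < C; ++c) Si[c] = Sn[c] + bi * xt[c] - ai * y[c];
    }
    {
      double* Sl = &S[(size_t)(ns - 1) * C];
      const double bl = bb[ns], al = aa[ns];
      for (int c = 0; c < C; ++c) Sl[c] = bl * xt[c] - al * y[c];
    }
    for (int c = 0; c < C; ++c) xt[c] = y[c];
  }
}

// Zero-phase filtering of every channel of a channels x samples matrix:
// forward pass over the signal extended with 2*max(nb,na) zero samples,
// then a backward pass, then truncation -- the same scheme as
// signal::filtfilt, with a[0]-normalized coefficients.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericMatrix X, NumericVector bv,
                           NumericVector av) {
  const int C = X.nrow(), n = X.ncol();
  std::vector<double> b(bv.begin(), bv.end()), a(av.begin(), av.end());
  const int pad = 2 * (int)std::max(b.size(), a.size());
  const int ntot = n + pad;
  std::vector<double> buf((size_t)C * ntot, 0.0);
  for (int t = 0; t < n; ++t) {
    for (int c = 0; c < C; ++c) buf[(size_t)t * C + c] = X(c, t);
  }
  iir_pass(buf, C, ntot, b, a, +1);
  iir_pass(buf, C, ntot, b, a, -1);
  NumericMatrix out(C, n);
  for (int t = 0; t < n; ++t) {
    for (int c = 0; c < C; ++c) out(c, t) = buf[(size_t)t * C + c];
  }
  return out;
}
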