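#include <Rcpp.h>
using namespace Rcpp;

// Peak |delay-and-sum| metric for a set of integer shifts.
//
// x: electrodes x samples matrix (one epoch, artifacts already blanked).
// shifts: integer shifts s (samples); electrode e is advanced by e*s samples,
//   i.e. out(t) = sum_e x(e, t + e*s), zero-padded at the edges, so a wave
//   whose inter-electrode arrival delay equals s sums constructively.
// winStart/winEnd: 0-based half-open sample window over which the peak of the
//   absolute summed trace is taken.
// [[Rcpp::export(name = ".dsPeakMetric")]]
NumericVector dsPeakMetric(NumericMatrix x, IntegerVector shifts,
                           int winStart, int winEnd) {
  const int nE = x.nrow();
  const int n = x.ncol();
  const int nS = shifts.size();
  if (winStart < 0) winStart = 0;
  if (winEnd > n) winEnd = n;
  NumericVector out(nS);
  for (int k = 0; k < nS; ++k) {
    const int s = shifts[k];
    double best = 0.0;
    for (int t = winStart; t < winEnd; ++t) {
      double acc = 0.0;
      for (int e = 0; e < nE; ++e) {
        const int idx = t + e * s;
        if (idx >= 0 && idx < n) acc += x(e, idx);
      }
      const double a = std::fabs(acc);
      if (a > best) best = a;
    }
    out[k] = best;
  }
  return out;
}
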