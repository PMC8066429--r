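#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Bin layout shared with the R side: m = floor(window/bin), nbins = 2m + 1,
// bin centers at k*bin for k in -m..m, half-open edges [c - bin/2, c + bin/2).
// Times are in seconds, lags and bin widths in milliseconds.

static void lag_hist_core(const double* ref, int nr,
                          const double* tgt, int nt,
                          double bin_ms, double window_ms,
                          double* counts, int m) {
  const double W = (m + 0.5) * bin_ms / 1000.0; // seconds, exclusive upper edge
  int lo = 0;
  for (int i = 0; i < nr; ++i) {
    const double t = ref[i];
    while (lo < nt && tgt[lo] < t - W) ++lo;
    for (int j = lo; j < nt && tgt[j] < t + W; ++j) {
      const double lag_ms = (tgt[j] - t) * 1000.0;
      const int k = (int)std::floor(lag_ms / bin_ms + 0.5);
      if (k >= -m && k <= m) counts[k + m] += 1.0;
    }
  }
}

// [[Rcpp::export(name = ".cppLagHist")]]
NumericVector cppLagHist(NumericVector ref, NumericVector target,
                         double bin_ms, double window_ms) {
  const int m = (int)std::floor(window_ms / bin_ms + 1e-9);
  NumericVector counts(2 * m + 1);
  lag_hist_core(REAL(ref), ref.size(), REAL(target), target.size(),
                bin_ms, window_ms, REAL(counts), m);
  return counts;
}

// One row per surrogate: every target spike independently jittered by
// Uniform(-jitter_ms, +jitter_ms), then re-binned against the fixed reference.
// Uses R's RNG so set.seed() on the R side makes the bands reproducible.
// [[Rcpp::export(name = ".cppJitterSurrogates")]]
NumericMatrix cppJitterSurrogates(NumericVector ref, NumericVector target,
                                  double bin_ms, double window_ms,
                                  double jitter_ms, int n_surrogates) {
  const int m = (int)std::floor(window_ms / bin_ms + 1e-9);
  const int nbins = 2 * m + 1;
  const int nt = target.size();
  NumericMatrix out(n_surrogates, nbins);
  std::vector<double> jit(nt);
  std::vector<double> row(nbins);
  const double js = jitter_ms / 1000.0;
  for (int s = 0; s < n_surrogates; ++s) {
    for (int j = 0; j < nt; ++j) jit[j] = target[j] + R::runif(-js, js);
    std::sort(jit.begin(), jit.end());
    std::fill(row.begin(), row.end(), 0.0);
    lag_hist_core(REAL(ref), ref.size(), jit.data(), nt, bin_ms, window_ms,
                  row.data(), m);
    for (int b = 0; b < nbins; ++b) out(s, b) = row[b];
  }
  return out;
}
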