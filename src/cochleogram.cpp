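#include <Rcpp.h>
using namespace Rcpp;

// Cochleogram core: for each channel, a cascade of `n_stages` identical
// two-pole resonator stages (all-pole gammatone approximation), half-wave
// rectification, a biquad low-pass envelope smoother, power-law
// compression, and frame accumulation. Returns the n_frames x n_channels
// frame-averaged energy matrix.
//
// x:        waveform
// a1, a2:   per-channel denominator coefficients (1 + a1 z^-1 + a2 z^-2)
// gain:     per-channel per-stage numerator gain
// env_b, env_a: envelope low-pass biquad (length 3 each, a[0] == 1)
// fidx:     1-based frame index per sample (0 = discarded partial frame)
// n_frames: number of frames
// compression: power-law exponent
// [[Rcpp::export(name = ".cochleogram_core")]]
NumericMatrix cochleogram_core(NumericVector x, NumericVector a1,
                               NumericVector a2, NumericVector gain,
                               NumericVector env_b, NumericVector env_a,
                               IntegerVector fidx, int n_frames,
                               double compression, int decim = 1,
                               int n_stages = 4) {
  const int n = x.size();
  const int K = a1.size();
  NumericMatrix out(n_frames, K);
  NumericVector counts(n_frames);
  // the smoothed envelope is band-limited, so compression and frame
  // averaging are evaluated on every decim-th sample only
  for (int i = 0; i < n; i += decim) {
    if (fidx[i] > 0) counts[fidx[i] - 1] += 1.0;
  }
  std::vector<double> y(n);
  for (int k = 0; k < K; ++k) {
    const double c1 = a1[k], c2 = a2[k], g = gain[k];
    for (int i = 0; i < n; ++i) y[i] = x[i];
    for (int s = 0; s < n_stages; ++s) {
      double y1 = 0.0, y2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = g * y[i] - c1 * y1 - c2 * y2;
        // flush denormals: silent stretches otherwise leave sub-normal
        // tails in the resonator state, stalling the FPU
        if (v < 1e-25 && v > -1e-25) v = 0.0;
        y[i] = v;
        y2 = y1;
        y1 = v;
      }
    }
    // half-wave rectify + envelope low-pass (direct form I) + compress,
    // accumulating frame sums on the fly
    const double b0 = env_b[0], b1 = env_b[1], b2 = env_b[2];
    const double d1 = env_a[1], d2 = env_a[2];
    double x1 = 0.0, x2 = 0.0, w1 = 0.0, w2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double u = y[i] > 0.0 ? y[i] : 0.0;
      double w = b0 * u + b1 * x1 + b2 * x2 - d1 * w1 - d2 * w2;
      if (w < 1e-25 && w > -1e-25) w = 0.0;
      x2 = x1; x1 = u;
      w2 = w1; w1 = w;
      if (i % decim == 0 && fidx[i] > 0) {
        double e = w > 0.0 ? std::pow(w, compression) : 0.0;
        out(fidx[i] - 1, k) += e;
      }
    }
    for (int f = 0; f < n_frames; ++f) {
      if (counts[f] > 0) out(f, k) /= counts[f];
    }
  }
  return out;
}
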