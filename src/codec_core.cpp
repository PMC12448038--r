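#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// minimal magnitude bits covering all values 0..limit
static inline int bits_needed_i(long long limit) {
  int k = 0;
  while (limit > 0) { ++k; limit >>= 1; }
  return k;
}

static inline int select_shift_i(double sigma, double f, int payload_bits,
                                 int max_shift) {
  long long lim = (long long) std::llround(f * sigma);
  int s = bits_needed_i(lim) - (payload_bits - 1);
  if (s < 0) s = 0;
  if (s > max_shift) s = max_shift;
  return s;
}

static inline long long round_half_away(double x) {
  return (long long)(x >= 0 ? std::floor(x + 0.5) : std::ceil(x - 0.5));
}

// Closed-loop adaptive delta encoder over a whole stream of signed 24-bit
// codes. Window layout: sample 1 of each stats window is a keyframe
// (transmitted absolutely); the remaining samples of the window are
// quantised first differences against the encoder's own reconstruction.
// Shifts are per channel, constant within a window, selected from the
// previous window's first-difference standard deviation.
// [[Rcpp::export(name = ".codec_encode_core")]]
List codec_encode_core(IntegerMatrix codes, int payload_bits, double safety,
                       int max_shift, int window, int first_shift) {
  const int nch = codes.nrow(), n = codes.ncol();
  const int nwin = (n + window - 1) / window;
  const long long qmax = (1LL << (payload_bits - 1)) - 1;

  IntegerMatrix symbols(nch, n), recon(nch, n), shifts(nch, nwin);
  NumericMatrix sigma(nch, nwin);
  int n_saturated = 0;

  // per-window first-difference population SD of the *input* codes
  for (int w = 0; w < nwin; ++w) {
    int t0 = w * window, t1 = std::min(n, t0 + window);
    int nd = t1 - t0 - 1;
    for (int c = 0; c < nch; ++c) {
      if (nd <= 0) { sigma(c, w) = 0.0; continue; }
      double s1 = 0, s2 = 0;
      for (int t = t0 + 1; t < t1; ++t) {
        double d = (double) codes(c, t) - codes(c, t - 1);
        s1 += d; s2 += d * d;
      }
      double m = s1 / nd;
      double v = s2 / nd - m * m;
      sigma(c, w) = v > 0 ? std::sqrt(v) : 0.0;
    }
  }

  for (int c = 0; c < nch; ++c) {
    long long prev = 0;
    for (int w = 0; w < nwin; ++w) {
      int s = (w == 0) ? first_shift
                       : select_shift_i(sigma(c, w - 1), safety, payload_bits,
                                        max_shift);
      shifts(c, w) = s;
      const long long step = 1LL << s;
      int t0 = w * window, t1 = std::min(n, t0 + window);
      for (int t = t0; t < t1; ++t) {
        if (t == t0) {            // keyframe: absolute value, exact
          prev = codes(c, t);
          recon(c, t) = (int) prev;
          symbols(c, t) = NA_INTEGER;
          continue;
        }
        long long d = (long long) codes(c, t) - prev;
        long long q = round_half_away((double) d / step);
        if (q > qmax) { q = qmax; ++n_saturated; }
        else if (q < -qmax) { q = -qmax; ++n_saturated; }
        prev += q * step;
        symbols(c, t) = (int) q;
        recon(c, t) = (int) prev;
      }
    }
  }

  return List::create(_["symbols"] = symbols, _["recon"] = recon,
                      _["shifts"] = shifts, _["sigma"] = sigma,
                      _["n_saturated"] = n_saturated);
}
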