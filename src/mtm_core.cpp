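#include <Rcpp.h>
#include <vector>
#include <complex>
#include <cmath>
using namespace Rcpp;

// iterative radix-2 complex FFT, in place; n = power of two
static void fft_pow2(std::vector<std::complex<double> >& a,
                     const std::vector<std::complex<double> >& tw) {
  const size_t n = a.size();
  for (size_t i = 1, j = 0; i < n; ++i) {
    size_t bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[i], a[j]);
  }
  for (size_t len = 2; len <= n; len <<= 1) {
    size_t step = n / len;
    for (size_t i = 0; i < n; i += len) {
      for (size_t k = 0; k < len / 2; ++k) {
        std::complex<double> w = tw[k * step];
        std::complex<double> u = a[i + k];
        std::complex<double> v = a[i + k + len / 2] * w;
        a[i + k] = u + v;
        a[i + k + len / 2] = u - v;
      }
    }
  }
}

// Multitaper eigenspectrum accumulation: for each column of x (a real time
// series) return the mean over tapers of |FFT(taper * x)|^2 on the one-sided
// grid of a zero-padded power-of-two FFT (nfft). Two real columns are packed
// into one complex FFT and unpacked by conjugate symmetry.
// [[Rcpp::export(name = ".mtm_accum")]]
NumericMatrix mtm_accum(NumericMatrix x, NumericMatrix tapers, int nfft) {
  const int n = x.nrow(), m = x.ncol(), K = tapers.ncol();
  if (tapers.nrow() != n) stop("taper length must match series length");
  if (nfft < n || (nfft & (nfft - 1)) != 0) stop("nfft must be a power of two >= n");
  const int nf = nfft / 2 + 1;
  std::vector<std::complex<double> > tw(nfft), buf(nfft);
  for (int k = 0; k < nfft; ++k)
    tw[k] = std::polar(1.0, -2.0 * M_PI * k / nfft);
  NumericMatrix out(nf, m);
  for (int j = 0; j < m; j += 2) {
    const bool pair = (j + 1 < m);
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double t = tapers(i, k);
        buf[i] = std::complex<double>(x(i, j) * t,
                                      pair ? x(i, j + 1) * t : 0.0);
      }
      std::fill(buf.begin() + n, buf.end(), std::complex<double>(0.0, 0.0));
      fft_pow2(buf, tw);
      for (int f = 0; f < nf; ++f) {
        std::complex<double> bf = buf[f];
        std::complex<double> bc = std::conj(buf[(nfft - f) % nfft]);
        std::complex<double> x1 = 0.5 * (bf + bc);
        out(f, j) += std::norm(x1);
        if (pair) {
          std::complex<double> x2 =
            std::complex<double>(0.0, -0.5) * (bf - bc);
          out(f, j + 1) += std::norm(x2);
        }
      }
    }
  }
  for (int j = 0; j < m; ++j)
    for (int f = 0; f < nf; ++f) out(f, j) /= K;
  return out;
}
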