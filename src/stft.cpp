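// Short-time per-bin power kernel. One-sided, window-corrected so that the
// column sum of the returned matrix equals the windowed mean square of the
// frame (Parseval); everything downstream (band powers, wind screening)
// consumes this grid.
//
// Uses an in-place iterative radix-2 FFT with a precomputed twiddle table,
// packing two real frames into one complex transform (the usual two-for-one
// real-FFT trick), which is much faster than generic FFT calls for the
// many short frames an STFT needs.
#include <RcppArmadillo.h>
#include <complex>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef std::complex<double> cplx;

static void fft_radix2(std::vector<cplx>& a, const std::vector<cplx>& tw) {
  const int n = static_cast<int>(a.size());
  // bit-reversal permutation
  for (int i = 1, j = 0; i < n; ++i) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[i], a[j]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    const int step = n / len;
    const int half = len >> 1;
    for (int i = 0; i < n; i += len) {
      for (int k = 0; k < half; ++k) {
        const cplx u = a[i + k];
        const cplx v = a[i + k + half] * tw[k * step];
        a[i + k] = u + v;
        a[i + k + half] = u - v;
      }
    }
  }
}

// x: samples; win: window taper (length = frame size, power of two);
// hop: samples between frame starts. Returns (nbins x nframes),
// nbins = n/2 + 1.
// [[Rcpp::export(name = ".stft_power")]]
arma::mat stft_power(const arma::vec& x, const arma::vec& win, const int hop) {
  const int n = static_cast<int>(win.n_elem);
  const int len = static_cast<int>(x.n_elem);
  if (len < n) stop("signal shorter than one analysis window");
  if (n < 2 || (n & (n - 1)) != 0) {
    stop("window length must be a power of two");
  }
  const int nframes = (len - n) / hop + 1;
  const int nbins = n / 2 + 1;

  std::vector<cplx> tw(n / 2);
  for (int k = 0; k < n / 2; ++k) {
    const double ang = -2.0 * M_PI * k / n;
    tw[k] = cplx(std::cos(ang), std::sin(ang));
  }

  // scale so sum over one-sided bins = (1/sum(w^2)) * sum((w*x)^2)
  const double wss = arma::accu(win % win);
  const double norm = 1.0 / (static_cast<double>(n) * wss);

  arma::mat P(nbins, nframes);
  std::vector<cplx> z(n);

  for (int j = 0; j < nframes; j += 2) {
    const bool pair = (j + 1 < nframes);
    const double* x1 = x.memptr() + j * hop;
    const double* x2 = pair ? x.memptr() + (j + 1) * hop : nullptr;
    for (int i = 0; i < n; ++i) {
      z[i] = cplx(win[i] * x1[i], pair ? win[i] * x2[i] : 0.0);
    }
    fft_radix2(z, tw);
    // unpack the two real spectra: X1 = (Z[k] + conj(Z[n-k]))/2,
    // X2 = (Z[k] - conj(Z[n-k]))/(2i)
    for (int k = 0; k < nbins; ++k) {
      const cplx zk = z[k];
      const cplx zc = std::conj(z[(n - k) % n]);
      const cplx X1 = 0.5 * (zk + zc);
      const cplx X2 = cplx(0.0, -0.5) * (zk - zc);
      const double side = (k == 0 || k == n / 2) ? 1.0 : 2.0;
      P(k, j) = std::norm(X1) * norm * side;
      if (pair) P(k, j + 1) = std::norm(X2) * norm * side;
    }
  }
  return P;
}
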