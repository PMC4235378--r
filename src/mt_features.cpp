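// Multitaper short-time spectral features for ultrasonic audio.
//
// The detector only needs, per analysis frame: Shannon entropy of the
// normalized ultrasonic power vector, summed sonic and ultrasonic band
// power, and the peak ultrasonic bin. Computing these in one streaming
// pass keeps memory flat for hour-scale 250 kHz recordings.
//
// Real-input FFTs are packed two-per-complex-FFT (tapers 1+2 share one
// transform; taper 3 packs adjacent frames), halving transform count.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline void unpack_pair_power(const arma::cx_mat& Z, int nfft,
                                     int bin_lo, int bin_hi,
                                     int col, double* pa, double* pb) {
  // Z col holds fft(a + i*b) for real a, b. Recover |A_k|^2 and |B_k|^2
  // for k in [bin_lo, bin_hi] (0 < k < nfft assumed).
  const arma::cx_double* z = Z.colptr(col);
  for (int k = bin_lo; k <= bin_hi; ++k) {
    arma::cx_double zk = z[k];
    arma::cx_double zc = std::conj(z[nfft - k]);
    arma::cx_double A = 0.5 * (zk + zc);
    arma::cx_double B = arma::cx_double(0.0, -0.5) * (zk - zc);
    pa[k - bin_lo] += std::norm(A);
    pb[k - bin_lo] += std::norm(B);
  }
}

// [[Rcpp::export]]
List mt_frame_features_cpp(const arma::vec& x, const arma::mat& tapers,
                           const double step, const int nfft,
                           const int ultra_lo, const int ultra_hi,
                           const int sonic_lo, const int sonic_hi,
                           const bool return_power, const int chunk_frames) {
  const int n = (int)tapers.n_rows;
  const int K = (int)tapers.n_cols;
  const long long len = (long long)x.n_elem;
  if (len < n) stop("signal shorter than one analysis window");
  if (nfft < n) stop("nfft must be >= window length");
  if (ultra_lo <= 0 || ultra_hi >= nfft || sonic_lo <= 0)
    stop("frequency bins out of range");
  if (step <= 0) stop("step must be positive");
  const long long nframes = (long long)std::floor((double)(len - n) / step) + 1;
  const int bin_lo = std::min(sonic_lo, ultra_lo);
  const int bin_hi = std::max(sonic_hi, ultra_hi);
  const int nb = bin_hi - bin_lo + 1;
  const int nu = ultra_hi - ultra_lo + 1;

  arma::vec entropy(nframes), sonic_pow(nframes), ultra_pow(nframes);
  arma::ivec peak_bin(nframes);
  arma::mat power_out;
  if (return_power) power_out.set_size(nu, nframes);

  std::vector<double> pw(nb);
  const double log2e = 1.0 / std::log(2.0);

  for (long long f0 = 0; f0 < nframes; f0 += chunk_frames) {
    const int m = (int)std::min((long long)chunk_frames, nframes - f0);

    // tapers 0 (real part) and 1 (imag part, if present)
    arma::cx_mat C(nfft, m, arma::fill::zeros);
    for (int j = 0; j < m; ++j) {
      const double* xs = x.memptr() + (long long)std::llround((double)(f0 + j) * step);
      arma::cx_double* c = C.colptr(j);
      if (K >= 2) {
        const double* t0 = tapers.colptr(0);
        const double* t1 = tapers.colptr(1);
        for (int t = 0; t < n; ++t)
          c[t] = arma::cx_double(xs[t] * t0[t], xs[t] * t1[t]);
      } else {
        const double* t0 = tapers.colptr(0);
        for (int t = 0; t < n; ++t) c[t] = arma::cx_double(xs[t] * t0[t], 0.0);
      }
    }
    arma::cx_mat Z1 = arma::fft(C);

    // remaining tapers packed over adjacent frame pairs
    arma::cx_mat Z2;
    int extra = K - 2;  // number of tapers beyond the first pair
    if (extra > 0) {
      if (extra > 1) stop("at most 3 tapers supported by this kernel");
      const int mc = (m + 1) / 2;
      arma::cx_mat C2(nfft, mc, arma::fill::zeros);
      const double* t2 = tapers.colptr(2);
      for (int c2 = 0; c2 < mc; ++c2) {
        const int ja = 2 * c2, jb = 2 * c2 + 1;
        const double* xa = x.memptr() + (long long)std::llround((double)(f0 + ja) * step);
        const double* xb = (jb < m) ? x.memptr() + (long long)std::llround((double)(f0 + jb) * step) : nullptr;
        arma::cx_double* c = C2.colptr(c2);
        for (int t = 0; t < n; ++t)
          c[t] = arma::cx_double(xa[t] * t2[t], xb ? xb[t] * t2[t] : 0.0);
      }
      Z2 = arma::fft(C2);
    }

    std::vector<double> pw2(nb);
    for (int j = 0; j < m; ++j) {
      std::fill(pw.begin(), pw.end(), 0.0);
      std::fill(pw2.begin(), pw2.end(), 0.0);
      if (K >= 2) {
        unpack_pair_power(Z1, nfft, bin_lo, bin_hi, j, pw.data(), pw2.data());
        for (int k = 0; k < nb; ++k) pw[k] += pw2[k];
      } else {
        const arma::cx_double* z = Z1.colptr(j);
        for (int k = bin_lo; k <= bin_hi; ++k) pw[k - bin_lo] += std::norm(z[k]);
      }
      if (K == 3) {
        std::fill(pw2.begin(), pw2.end(), 0.0);
        std::vector<double> pwb(nb, 0.0);
        unpack_pair_power(Z2, nfft, bin_lo, bin_hi, j / 2, pw2.data(), pwb.data());
        if (j % 2 == 0)
          for (int k = 0; k < nb; ++k) pw[k] += pw2[k];
        else
          for (int k = 0; k < nb; ++k) pw[k] += pwb[k];
      }
      // mean over tapers
      const double invK = 1.0 / K;
      double s_sonic = 0.0, s_ultra = 0.0, pmax = -1.0;
      int kmax = ultra_lo;
      for (int k = sonic_lo; k <= sonic_hi; ++k) s_sonic += pw[k - bin_lo];
      for (int k = ultra_lo; k <= ultra_hi; ++k) {
        const double p = pw[k - bin_lo];
        s_ultra += p;
        if (p > pmax) { pmax = p; kmax = k; }
      }
      double H = 0.0;
      if (s_ultra > 0.0) {
        for (int k = ultra_lo; k <= ultra_hi; ++k) {
          const double p = pw[k - bin_lo] / s_ultra;
          if (p > 0.0) H -= p * std::log(p) * log2e;
        }
      } else {
        H = NA_REAL;
      }
      const long long fi = f0 + j;
      entropy(fi) = H;
      sonic_pow(fi) = s_sonic * invK;
      ultra_pow(fi) = s_ultra * invK;
      peak_bin(fi) = kmax;
      if (return_power)
        for (int k = 0; k < nu; ++k)
          power_out(k, fi) = pw[ultra_lo - bin_lo + k] * invK;
    }
    Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["entropy"] = entropy, _["sonic_power"] = sonic_pow,
      _["ultra_power"] = ultra_pow, _["peak_bin"] = peak_bin);
  if (return_power) out["power"] = power_out;
  return out;
}
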