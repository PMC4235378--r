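#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem. Tapers are
#' unit-energy and polarity-standardized (symmetric tapers have positive
#' mean, antisymmetric tapers positive initial slope).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (window duration times bandwidth); the
#'   usual choice takes `k <= 2*nw - 1` well-concentrated tapers, so `nw = 2`
#'   pairs with 3 tapers.
#' @param k number of tapers.
#' @return numeric matrix `n` x `k`, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot_scalar_pos(n, "n"); stopifnot_scalar_pos(nw, "nw")
  if (k < 1) abort("`k` must be >= 1")
  if (k > 2 * nw - 1 + 1e-9)
    warn("requesting more tapers than 2*nw - 1; extra tapers are poorly concentrated")
  w <- nw / n
  t <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) != 0) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Spectrogram parameters for ultrasonic vocalization detection
#'
#' Defaults follow standard multitaper sonogram settings for rodent USV work:
#' 2 ms windows stepped every 0.25 ms, 1 kHz bandwidth, 3 tapers; entropy is
#' evaluated over the 18-100 kHz band and broadband noise is flagged by power
#' in the 5-18 kHz sonic band.
#'
#' @param window analysis window length, seconds.
#' @param step window step, seconds (must be <= `window`).
#' @param bandwidth multitaper bandwidth, Hz; the time-bandwidth product is
#'   `window * bandwidth`.
#' @param n_tapers number of Slepian tapers.
#' @param freq_lo,freq_hi ultrasonic band edges, kHz.
#' @param sonic_lo,sonic_hi sonic (noise-indicator) band edges, kHz.
#' @param freq_bin_hz target frequency-bin spacing, Hz; windows are zero-padded
#'   to reach it (the 2 ms default already gives 500 Hz).
#' @return list of class `usv_spectrogram_params`.
#' @export
spectrogram_params <- function(window = 0.002, step = 0.00025, bandwidth = 1000,
                               n_tapers = 3, freq_lo = 18, freq_hi = 100,
                               sonic_lo = 5, sonic_hi = 18, freq_bin_hz = 500) {
  if (step > window) abort("`step` must be <= `window`")
  if (freq_lo >= freq_hi) abort("`freq_lo` must be < `freq_hi`")
  if (n_tapers < 1) abort("`n_tapers` must be >= 1")
  structure(list(window = window, step = step, bandwidth = bandwidth,
                 n_tapers = n_tapers, freq_lo = freq_lo, freq_hi = freq_hi,
                 sonic_lo = sonic_lo, sonic_hi = sonic_hi,
                 freq_bin_hz = freq_bin_hz),
            class = "usv_spectrogram_params")
}

#' Shannon entropy of a power spectrum
#'
#' Normalizes a non-negative power vector to sum 1 and returns
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`. Low values
#' indicate narrowband (whistle-like) spectra, high values broadband noise.
#'
#' @param power non-negative numeric vector (or matrix, column-wise).
#' @return entropy in bits; for a matrix, one value per column.
#' @export
spectral_entropy <- function(power) {
  if (is.matrix(power)) return(apply(power, 2L, spectral_entropy))
  if (any(power < 0) || anyNA(power)) abort("power must be non-negative and finite")
  s <- sum(power)
  if (s == 0) abort("entropy undefined for an all-zero power vector")
  p <- power / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Multitaper spectral frames of an audio channel
#'
#' Slides a multitaper estimator along the waveform and returns one row per
#' frame with the quantities the entropy detector consumes: ultrasonic-band
#' spectral entropy, summed sonic and ultrasonic power, and the peak
#' ultrasonic frequency (the per-frame frequency track).
#'
#' @param audio numeric waveform, or a list with elements `samples` and `sr`.
#' @param sr sampling rate in Hz (ignored if `audio` carries one).
#' @param params [spectrogram_params()].
#' @param return_power if `TRUE`, attach the full ultrasonic power matrix
#'   (bins x frames) as attribute `power` with bin frequencies in attribute
#'   `freq_khz`. Meant for short signals; off by default.
#' @return tibble with columns `time` (window center, s), `entropy` (bits),
#'   `sonic_power`, `ultra_power`, `peak_freq` (kHz). Attributes: `n_bins`,
#'   `step`, `sr`, `params`.
#' @export
compute_spectrogram <- function(audio, sr = NULL, params = spectrogram_params(),
                                return_power = FALSE) {
  if (is.list(audio)) { sr <- audio$sr; audio <- audio$samples }
  if (is.null(sr)) abort("`sr` must be supplied")
  if (sr < 2000 * params$freq_hi)
    abort(sprintf("sampling rate %g Hz cannot represent the %g kHz band edge",
                  sr, params$freq_hi))
  win_n <- round(params$window * sr)
  step_n <- params$step * sr  # may be fractional; frame starts are rounded
  if (step_n < 1) abort("step below one sample")
  if (length(audio) < win_n) abort("audio shorter than one analysis window")
  nfft <- max(win_n, round(sr / params$freq_bin_hz))
  freq <- (0:(nfft - 1)) * sr / nfft / 1000  # kHz
  half <- floor(nfft / 2)
  ultra <- which(freq >= params$freq_lo & freq <= params$freq_hi &
                   seq_along(freq) <= half)
  sonic <- which(freq >= params$sonic_lo & freq < params$freq_lo &
                   seq_along(freq) <= half)
  if (length(ultra) < 2L) abort("ultrasonic band contains fewer than 2 bins")
  tap <- dpss_tapers(win_n, nw = params$window * params$bandwidth,
                     k = params$n_tapers)
  res <- mt_frame_features_cpp(as.numeric(audio), tap, step_n, as.integer(nfft),
                               min(ultra) - 1L, max(ultra) - 1L,
                               min(sonic) - 1L, max(sonic) - 1L,
                               return_power, 4096L)
  nf <- length(res$entropy)
  out <- tibble::tibble(
    time = (seq_len(nf) - 1) * params$step + params$window / 2,
    entropy = as.numeric(res$entropy),
    sonic_power = as.numeric(res$sonic_power),
    ultra_power = as.numeric(res$ultra_power),
    peak_freq = freq[as.integer(res$peak_bin) + 1L]
  )
  attr(out, "n_bins") <- length(ultra)
  attr(out, "step") <- step_n / sr
  attr(out, "sr") <- sr
  attr(out, "params") <- params
  if (return_power) {
    attr(out, "power") <- res$power
    attr(out, "freq_khz") <- freq[ultra]
  }
  out
}
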