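#' Parametric tubing transfer function
#'
#' First-order low-pass plus pure delay, the standard model for the pressure
#' distortion imposed by cannula-to-sensor tubing (fast fluctuations are
#' filtered down and the signal is delayed).
#'
#' @param fc_hz corner frequency, Hz (`Inf` gives unity magnitude).
#' @param delay_s pure delay, seconds.
#' @return object of class `usv_transfer_function`.
#' @export
tubing_tf <- function(fc_hz = 40, delay_s = 0.004) {
  structure(list(type = "parametric", fc_hz = fc_hz, delay_s = delay_s),
            class = "usv_transfer_function")
}

#' Identity transfer function
#' @return a [tubing_tf()] with unit gain and zero delay.
#' @export
identity_tf <- function() tubing_tf(fc_hz = Inf, delay_s = 0)

#' Complex gain of a transfer function at given frequencies
#'
#' @param tf a `usv_transfer_function` (parametric or tabulated).
#' @param freq_hz numeric vector of non-negative frequencies.
#' @return complex vector of gains.
#' @export
tf_gain <- function(tf, freq_hz) {
  if (tf$type == "parametric") {
    mag <- if (is.infinite(tf$fc_hz)) rep(1 + 0i, length(freq_hz))
           else 1 / (1 + 1i * freq_hz / tf$fc_hz)
    return(mag * exp(-2i * pi * freq_hz * tf$delay_s))
  }
  re <- approx(tf$freq_hz, Re(tf$gain), freq_hz, rule = 2)$y
  im <- approx(tf$freq_hz, Im(tf$gain), freq_hz, rule = 2)$y
  complex(real = re, imaginary = im)
}

# apply a transfer function to a real signal via FFT filtering; the signal is
# zero-padded to a 2-3-5-smooth length so the FFT never degenerates
apply_transfer_function <- function(x, sr, tf) {
  if (tf$type == "parametric" && is.infinite(tf$fc_hz) && tf$delay_s == 0)
    return(x)  # exact identity
  n0 <- length(x)
  n <- nextn(n0, c(2, 3, 5))
  X <- fft(c(x, rep(0, n - n0)))
  half <- floor(n / 2)
  fpos <- (0:half) * sr / n
  gpos <- tf_gain(tf, fpos)
  g <- complex(length.out = n)
  g[1:(half + 1)] <- gpos
  if (n > 1) g[seq(n, half + 2)] <- Conj(gpos[2:(n - half)])
  if (n %% 2 == 0) g[half + 1] <- complex(real = Re(gpos[half + 1]), imaginary = 0)
  Re(fft(X * g, inverse = TRUE))[seq_len(n0)] / n
}

#' Estimate a transfer function by Fourier deconvolution
#'
#' Divides the spectrum of the distorted recording by that of a time-aligned
#' broadband reference, with a regularization floor on reference-spectrum
#' magnitude to bound noise amplification in poorly excited bins.
#'
#' @param reference undistorted signal (e.g. sensor at the transducer output).
#' @param distorted same signal after passing through the tubing.
#' @param sr sampling rate, Hz.
#' @param floor_frac bins where the reference magnitude falls below
#'   `floor_frac * max` are regularized.
#' @return tabulated `usv_transfer_function` over 0 to `sr/2`.
#' @export
estimate_transfer_function <- function(reference, distorted, sr,
                                       floor_frac = 1e-3) {
  if (length(reference) != length(distorted))
    abort("reference and distorted traces must have equal length")
  n <- length(reference)
  X <- fft(reference); Y <- fft(distorted)
  half <- floor(n / 2)
  mag <- Mod(X)
  floor_mag <- floor_frac * max(mag)
  if (all(mag <= floor_mag))
    abort("reference spectrum below the regularization floor everywhere; ill-conditioned")
  G <- Y * Conj(X) / (mag^2 + floor_mag^2)
  structure(list(type = "tabulated",
                 freq_hz = (0:half) * sr / n,
                 gain = G[1:(half + 1)]),
            class = "usv_transfer_function")
}

#' Undo tubing distortion by inverse filtering
#'
#' Divides the raw trace's spectrum by the transfer function. Bins where the
#' transfer-function magnitude is below `floor_frac` of its maximum are floored
#' (magnitude clamped, phase kept) so the inverse stays bounded.
#'
#' @param raw distorted pressure trace.
#' @param sr sampling rate, Hz.
#' @param tf `usv_transfer_function`.
#' @param floor_frac regularization floor relative to `max(|tf|)`.
#' @return numeric vector, the reconstructed trace.
#' @export
correct_tubing_distortion <- function(raw, sr, tf, floor_frac = 1e-3) {
  n0 <- length(raw)
  n <- nextn(n0, c(2, 3, 5))
  raw <- c(raw, rep(0, n - n0))
  half <- floor(n / 2)
  fpos <- (0:half) * sr / n
  gpos <- tf_gain(tf, fpos)
  gmax <- max(Mod(gpos))
  if (gmax == 0) abort("transfer function is zero everywhere; cannot invert")
  lo <- Mod(gpos) < floor_frac * gmax
  gpos[lo] <- gpos[lo] / Mod(gpos[lo]) * (floor_frac * gmax)
  gpos[is.na(gpos)] <- floor_frac * gmax  # zero-magnitude bins have no phase
  g <- complex(length.out = n)
  g[1:(half + 1)] <- gpos
  if (n > 1) g[seq(n, half + 2)] <- Conj(gpos[2:(n - half)])
  if (n %% 2 == 0) g[half + 1] <- complex(real = Re(gpos[half + 1]), imaginary = 0)
  Re(fft(fft(raw) / g, inverse = TRUE))[seq_len(n0)] / n
}

#' Preprocess a raw intranasal-pressure trace
#'
#' Removes slow sensor drift (zero-phase 0.1 Hz high-pass Butterworth),
#' applies the conventional 400 Hz low-pass smoother, z-scores the result and
#' flips the sign so inhalations are positive (raw sensor traces record
#' inhalation as a pressure decrease).
#'
#' @param raw numeric pressure trace (raw sign convention).
#' @param sr sampling rate, Hz (1000 by default).
#' @param flip_sign flip so inhalation is positive (default `TRUE`).
#' @param drift_high_hz high-pass corner for drift removal.
#' @param smooth_low_hz low-pass corner; `NULL` or >= Nyquist disables.
#' @return numeric vector with attributes `sr`; mean 0, SD 1.
#' @export
preprocess_pressure <- function(raw, sr = 1000, flip_sign = TRUE,
                                drift_high_hz = 0.1, smooth_low_hz = 400) {
  if (length(raw) < 2 * sr) abort("need at least 2 s of pressure data")
  if (sd(raw) == 0) abort("constant pressure trace; zero variance")
  x <- raw
  if (!is.null(drift_high_hz) && drift_high_hz > 0) {
    hp <- signal::butter(2, drift_high_hz / (sr / 2), type = "high")
    x <- signal::filtfilt(hp, x)
  }
  if (!is.null(smooth_low_hz) && smooth_low_hz < sr / 2) {
    lp <- signal::butter(4, smooth_low_hz / (sr / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x <- (x - mean(x)) / sd(x)
  if (flip_sign) x <- -x
  attr(x, "sr") <- sr
  x
}

# threshold crossings with hysteresis. Returns interpolated crossing times of
# `thr` (seconds): upward crossings (inhalation onsets) and downward crossings
# (inhalation offsets), alternating and validated by +-hyst excursions.
threshold_crossings <- function(x, sr, thr = 0, hyst = 0.05) {
  hi <- x > thr + hyst
  lo <- x < thr - hyst
  st <- integer(length(x))
  st[hi] <- 1L; st[lo] <- -1L
  idx <- which(st != 0L)
  if (length(idx) < 2L) return(list(up = numeric(0), down = numeric(0)))
  s <- st[idx]
  r <- rle(s)
  run_start <- idx[cumsum(c(1L, r$lengths[-length(r$lengths)]))]
  run_end <- idx[cumsum(r$lengths)]
  up <- numeric(0); down <- numeric(0)
  for (k in seq_along(r$values)[-1]) {
    a <- run_end[k - 1L]; b <- run_start[k]
    if (r$values[k] == 1L) {  # -1 -> +1: upward crossing of thr in (a, b)
      j <- a:(b - 1L)
      cross <- j[x[j] <= thr & x[j + 1L] > thr]
      if (length(cross)) {
        j0 <- cross[length(cross)]
        up <- c(up, (j0 - 1 + (thr - x[j0]) / (x[j0 + 1L] - x[j0])) / sr)
      }
    } else {
      j <- a:(b - 1L)
      cross <- j[x[j] >= thr & x[j + 1L] < thr]
      if (length(cross)) {
        j0 <- cross[length(cross)]
        down <- c(down, (j0 - 1 + (thr - x[j0]) / (x[j0 + 1L] - x[j0])) / sr)
      }
    }
  }
  list(up = up, down = down)
}

#' Segment a preprocessed pressure trace into sniff cycles
#'
#' Inhalation onsets are positive-slope crossings of a fixed threshold and
#' inhalation offsets the following negative-slope crossings (sub-sample
#' linear interpolation, +-`hysteresis` validation). A sniff spans inhalation
#' onset to the next inhalation onset (= exhalation offset); cycles with
#' inhalation shorter than `min_inh` are rejected; the trailing incomplete
#' cycle is dropped. Instant rate is the reciprocal of the onset-to-onset
#' interval.
#'
#' @param trace preprocessed trace ([preprocess_pressure()]), inhalation
#'   positive.
#' @param sr sampling rate, Hz (taken from the trace attribute if present).
#' @param threshold crossing threshold, SD units.
#' @param hysteresis excursion required on both sides of the threshold before
#'   a crossing is accepted, SD units.
#' @param min_inh minimum inhalation duration, seconds.
#' @return tibble: `sniff_id`, `t_inh_on`, `t_inh_off`, `t_exh_off`,
#'   `inh_duration`, `exh_duration`, `duration`, `instant_rate`.
#' @export
segment_sniffs <- function(trace, sr = NULL, threshold = 0, hysteresis = 0.05,
                           min_inh = 0.020) {
  sr <- sr %||% attr(trace, "sr")
  if (is.null(sr)) abort("`sr` must be supplied")
  cr <- threshold_crossings(as.numeric(trace), sr, threshold, hysteresis)
  up <- cr$up; down <- cr$down
  if (length(up) < 2L)
    return(tibble::tibble(sniff_id = integer(), t_inh_on = numeric(),
                          t_inh_off = numeric(), t_exh_off = numeric(),
                          inh_duration = numeric(), exh_duration = numeric(),
                          duration = numeric(), instant_rate = numeric()))
  # pair each onset with the first offset after it, bounded by the next onset
  di <- findInterval(up, down) + 1L
  off <- ifelse(di <= length(down), down[di], NA_real_)
  nxt <- c(up[-1L], NA_real_)
  ok <- !is.na(off) & !is.na(nxt) & off < nxt
  out <- tibble::tibble(
    t_inh_on = up[ok], t_inh_off = off[ok], t_exh_off = nxt[ok])
  out <- dplyr::mutate(out,
    inh_duration = .data$t_inh_off - .data$t_inh_on,
    exh_duration = .data$t_exh_off - .data$t_inh_off,
    duration = .data$t_exh_off - .data$t_inh_on,
    instant_rate = 1 / .data$duration)
  out <- dplyr::filter(out, .data$inh_duration >= min_inh)
  dplyr::mutate(out, sniff_id = dplyr::row_number(), .before = 1L)
}

#' Warped phase within a sniff cycle
#'
#' Three-point morphing: each sniff's inhalation is mapped linearly onto
#' `[0, mean_inh_frac]` and its exhalation onto `[mean_inh_frac, 1]`, so that
#' phase 0 is inhalation onset, `mean_inh_frac` the inhalation-exhalation
#' transition, and 1 the exhalation offset, regardless of the individual
#' sniff's duration.
#'
#' @param t time(s) to evaluate, seconds; vectorized.
#' @param inh_on,inh_off,exh_off the sniff's landmarks (recycled).
#' @param mean_inh_frac population inhalation fraction, e.g. from
#'   [mean_inhalation_fraction()].
#' @return phases in `[0, 1]`.
#' @export
sniff_phase <- function(t, inh_on, inh_off, exh_off, mean_inh_frac) {
  if (any(t < inh_on - 1e-12 | t > exh_off + 1e-12))
    abort("t outside the sniff cycle")
  ifelse(t <= inh_off,
         mean_inh_frac * (t - inh_on) / (inh_off - inh_on),
         mean_inh_frac + (1 - mean_inh_frac) * (t - inh_off) / (exh_off - inh_off))
}

#' Population inhalation fraction for phase warping
#'
#' Ratio of the mean inhalation duration to the mean cycle duration across all
#' sniffs in a session; the phase assigned to the inhalation-exhalation
#' transition by [sniff_phase()].
#'
#' @param sniffs sniff table with `inh_duration` and `exh_duration`.
#' @return scalar in (0, 1).
#' @export
mean_inhalation_fraction <- function(sniffs) {
  mi <- mean(sniffs$inh_duration)
  me <- mean(sniffs$exh_duration)
  mi / (mi + me)
}

#' Ongoing sniff rate in sliding windows
#'
#' Mean instant rate of sniffs whose inhalation onset falls inside each 3 s
#' window. By default only silent sniffs contribute, so the measure reflects
#' the respiratory rhythm uncontaminated by call-induced prolongations;
#' windows containing no eligible sniff yield `NA`.
#'
#' @param sniffs sniff table with `t_inh_on`, `instant_rate`, and (if
#'   `silent_only`) `is_vocal`.
#' @param window window length, s.
#' @param stride window stride, s.
#' @param silent_only exclude vocal sniffs.
#' @param t_range length-2 session time range; defaults to the sniff span.
#' @return tibble: `time` (window center), `sniff_rate` (Hz), `n_sniffs`.
#' @export
ongoing_sniff_rate <- function(sniffs, window = 3, stride = 0.25,
                               silent_only = TRUE, t_range = NULL) {
  t_range <- t_range %||% range(sniffs$t_inh_on)
  centers <- seq(t_range[1] + window / 2, max(t_range[2] - window / 2,
                                              t_range[1] + window / 2), by = stride)
  use <- sniffs
  if (silent_only) {
    if (!"is_vocal" %in% names(use)) abort("sniffs must carry `is_vocal` for silent_only")
    use <- dplyr::filter(use, !.data$is_vocal)
  }
  use <- dplyr::filter(use, is.finite(.data$instant_rate))
  purrr::map_dfr(centers, function(ct) {
    inw <- use$t_inh_on >= ct - window / 2 & use$t_inh_on < ct + window / 2
    tibble::tibble(time = ct,
                   sniff_rate = if (any(inw)) mean(use$instant_rate[inw]) else NA_real_,
                   n_sniffs = sum(inw))
  })
}
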