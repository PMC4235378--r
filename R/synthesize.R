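#' Render ground-truth calls as two-channel ultrasonic audio
#'
#' Each subject's calls are rendered as smooth frequency-modulated narrowband
#' whistles inside the configured band, added at `snr_db` (tone power over
#' 18-100 kHz band noise power) to that subject's microphone channel, and at
#' `crosstalk_db` attenuation to the far channel. Raised-cosine amplitude
#' ramps (0.5 ms) avoid onset/offset clicks; sub-syllable gaps silence the
#' tone without interrupting the frequency contour.
#'
#' @param truths list with one element per subject, each the result of
#'   [inject_calls()] (uses `$emissions` and `$calls`).
#' @param config [generator_config()].
#' @param duration session duration, s.
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @param sr audio sampling rate; defaults to `config$audio_sr`.
#' @return list of channels, one per subject, each `list(samples, sr)`.
#' @export
synthesize_audio <- function(truths, config, duration,
                             seed = config$seed + 2L, sr = config$audio_sr) {
  band <- config$call_freq_band_khz * 1000
  if (sr < 2 * band[2])
    abort(sprintf("sampling rate %g Hz violates Nyquist for the %g kHz band",
                  sr, band[2] / 1000))
  if (!is.null(seed)) set.seed(seed)
  # prolongations shift landmarks beyond the nominal duration; cover them
  t_end <- max(duration,
               max(purrr::map_dbl(truths,
                                  ~max(.x$sniffs$t_exh_off, 0))) + 0.05)
  n <- round(t_end * sr)
  n_sub <- length(truths)

  # tone amplitude from SNR relative to white-noise power inside the
  # ultrasonic detection band (18 kHz to min(100 kHz, Nyquist))
  noise_sd <- 1
  band_det <- c(18e3, min(100e3, sr / 2))
  p_noise_band <- noise_sd^2 * (band_det[2] - band_det[1]) / (sr / 2)
  amp <- sqrt(2 * 10^(config$snr_db / 10) * p_noise_band)
  g_cross <- if (is.infinite(config$crosstalk_db) && config$crosstalk_db < 0) 0
             else 10^(config$crosstalk_db / 20)

  # plain top-level vectors so subassignment stays in place (no copies of
  # hour-scale waveforms)
  waves <- vector("list", n_sub)
  for (s in seq_len(n_sub)) waves[[s]] <- rnorm(n, 0, noise_sd)

  ramp_n <- round(0.0005 * sr)
  for (s in seq_len(n_sub)) {
    calls <- truths[[s]]$calls
    emis <- truths[[s]]$emissions
    if (nrow(calls) == 0L) next
    for (ci in seq_len(nrow(calls))) {
      i0 <- max(1L, floor(calls$onset[ci] * sr) + 1L)
      i1 <- min(n, ceiling(calls$offset[ci] * sr))
      if (i1 <= i0) next
      m <- i1 - i0 + 1L
      tt <- (seq_len(m) - 1) / sr
      # smooth FM contour: spline through random knots inside the band
      dur <- calls$duration[ci]
      n_knot <- max(3L, ceiling(dur / 0.015))
      margin <- 0.1 * diff(band)
      fk <- runif(n_knot, band[1] + margin, band[2] - margin)
      fc <- spline(seq(0, dur, length.out = n_knot), fk, xout = tt)$y
      fc <- pmin(pmax(fc, band[1]), band[2])
      phase <- 2 * pi * cumsum(fc) / sr + runif(1L, 0, 2 * pi)
      tone <- sin(phase)
      # envelope: on during emission segments, raised-cosine edges
      env <- numeric(m)
      segs <- emis[emis$call_id == calls$call_id[ci], , drop = FALSE]
      for (e in seq_len(nrow(segs))) {
        j0 <- max(1L, floor(segs$onset[e] * sr) + 1L - i0 + 1L)
        j1 <- min(m, ceiling(segs$offset[e] * sr) - i0 + 1L)
        if (j1 <= j0) next
        env[j0:j1] <- 1
        k <- min(ramp_n, (j1 - j0) %/% 2L)
        if (k > 1L) {
          w <- 0.5 * (1 - cos(pi * (seq_len(k) - 1) / (k - 1)))
          env[j0:(j0 + k - 1L)] <- pmin(env[j0:(j0 + k - 1L)], w)
          env[(j1 - k + 1L):j1] <- pmin(env[(j1 - k + 1L):j1], rev(w))
        }
      }
      wave <- amp * env * tone
      waves[[s]][i0:i1] <- waves[[s]][i0:i1] + wave
      if (g_cross > 0 && n_sub > 1L) {
        for (o in setdiff(seq_len(n_sub), s))
          waves[[o]][i0:i1] <- waves[[o]][i0:i1] + g_cross * wave
      }
    }
  }
  purrr::map(waves, function(w) list(samples = w, sr = sr))
}

#' Render a ground-truth sniff train as an intranasal-pressure trace
#'
#' Silent sniffs are near-sinusoidal (inhalation lobe, exhalation lobe); a
#' vocal sniff's exhalation instead opens with a near-zero-flow plateau
#' (|pressure| below 20% of the exhalation peak) lasting until the call
#' offset, followed by the exhalation peak. The clean trace uses the raw
#' sensor sign convention (inhalation = pressure decrease); the distorted
#' trace is the clean one passed through `config$tubing_tf`. Both are
#' returned at `config$pressure_sr`.
#'
#' @param truth result of [inject_calls()] (uses `$sniffs`).
#' @param config [generator_config()].
#' @param duration session duration, s.
#' @param seed RNG seed for sensor noise (defaults to `config$seed + 3`).
#' @return `list(clean, raw, sr)`: numeric traces (raw = tubing-distorted).
#' @export
synthesize_pressure <- function(truth, config, duration,
                                seed = config$seed + 3L) {
  sr <- config$pressure_sr
  if (!is.null(seed)) set.seed(seed)
  t_end <- max(duration, max(truth$sniffs$t_exh_off, 0) + 0.05)
  n <- round(t_end * sr)
  x <- numeric(n)  # internal convention: inhalation positive
  sn <- truth$sniffs
  a_exh <- 0.9
  d_plat <- config$plateau_frac * a_exh
  for (k in seq_len(nrow(sn))) {
    i0 <- floor(sn$t_inh_on[k] * sr) + 1L
    i1 <- min(n, ceiling(sn$t_exh_off[k] * sr))
    if (i1 < i0 || i0 > n) next
    tt <- (seq(i0, i1) - 1) / sr
    ti <- sn$t_inh_off[k]; te <- sn$t_exh_off[k]; t0 <- sn$t_inh_on[k]
    seg <- numeric(length(tt))
    ex <- tt >= ti
    vocal <- isTRUE(sn$is_vocal[k])
    if (vocal) {
      c1 <- min(sn$call_offset[k], te - 1e-3)
      c0 <- min(max(sn$call_onset[k], ti + 1e-4), c1)
      tx <- tt[ex]
      ramp <- tx < c0
      seg[ex][ramp] <- -d_plat * 0.5 * (1 - cos(pi * (tx[ramp] - ti) / (c0 - ti)))
      plat <- tx >= c0 & tx <= c1
      seg[ex][plat] <- -d_plat
      rest <- tx > c1
      w <- (tx[rest] - c1) / (te - c1)
      seg[ex][rest] <- -(a_exh * sin(pi * w) + d_plat * (1 - w))
      area_exh <- d_plat * (c0 - ti) / 2 + d_plat * (c1 - c0) +
        (te - c1) * (a_exh * 2 / pi + d_plat / 2)
    } else {
      w <- (tt[ex] - ti) / (te - ti)
      seg[ex] <- -a_exh * sin(pi * w)
      area_exh <- a_exh * 2 / pi * (te - ti)
    }
    # equal-tidal-volume inhalation: lobe area matches the exhalation area,
    # so the session mean stays near zero and z-scoring preserves the
    # zero-flow baseline
    a_inh <- area_exh / (2 / pi * (ti - t0))
    inh <- !ex
    seg[inh] <- a_inh * sin(pi * (tt[inh] - t0) / (ti - t0))
    x[i0:i1] <- seg
  }
  x <- x + rnorm(n, 0, config$pressure_noise_sd)
  clean <- -x  # raw sign convention: inhalation = decrease
  raw <- apply_transfer_function(clean, sr, config$tubing_tf)
  list(clean = clean, raw = raw, sr = sr)
}

#' Simulate a complete recording session
#'
#' Chains [generate_sniff_train()], [inject_calls()], [synthesize_pressure()]
#' and (optionally) [synthesize_audio()] for one or two subjects, returning
#' ground truth alongside the rendered signals. With a fixed seed the output
#' is bit-identical across runs.
#'
#' @param config [generator_config()].
#' @param duration session duration, s.
#' @param n_subjects 1 or 2.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param audio render audio channels (the expensive part)?
#' @return object of class `usv_session`: list with `subjects` (per subject:
#'   `sniffs`, `calls`, `emissions`, `pressure`), `audio` (list of channels or
#'   `NULL`), `config`, `duration`, `seed`.
#' @export
simulate_session <- function(config = generator_config(), duration = 60,
                             n_subjects = 1L, seed = config$seed,
                             audio = TRUE) {
  if (!n_subjects %in% 1:2) abort("n_subjects must be 1 or 2")
  subjects <- purrr::map(seq_len(n_subjects), function(s) {
    st <- generate_sniff_train(config, duration, seed = seed_from(seed, 10 + s))
    tr <- inject_calls(st, config, seed = seed_from(seed, 20 + s))
    tr$pressure <- synthesize_pressure(tr, config, duration,
                                       seed = seed_from(seed, 30 + s))
    tr
  })
  aud <- if (audio)
    synthesize_audio(subjects, config, duration, seed = seed_from(seed, 40))
  else NULL
  structure(list(subjects = subjects, audio = aud, config = config,
                 duration = duration, seed = seed),
            class = "usv_session")
}
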