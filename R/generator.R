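#' Configuration for the synthetic session generator
#'
#' Builds the parameter set used to simulate paired ultrasonic audio and
#' intranasal-pressure recordings with full ground truth. The defaults encode
#' the statistical structure the analysis assumes: alternation between passive
#' (~2 Hz) and active (~8 Hz) breathing with exponential regime dwell times,
#' calls restricted to the post-inhalation portion of exhalations of actively
#' sniffing animals, exhalation prolongation proportional to call duration
#' (slope 0.85 ms/ms for the rat preset, 0.32 for the mouse preset), brief
#' (<20 ms) silent gaps inside calls, narrowband frequency-modulated whistles
#' (30-90 kHz rat, 50-100 kHz mouse), attenuated microphone crosstalk, and
#' low-pass/delay distortion of the pressure signal by sensor tubing.
#'
#' Call emission probability follows, for the rat preset, a latent rate that
#' fluctuates smoothly with a 1.5 s FWHM timescale; the mouse preset instead
#' uses a persistent two-state bout process, reflecting the species difference
#' in bout statistics.
#'
#' @param species `"rat"` or `"mouse"`; selects preset defaults.
#' @param ... named overrides for any field listed below.
#' @returns A list of class `usv_generator_config` with fields:
#' \describe{
#'   \item{passive_rate_mean, active_rate_mean}{regime mean sniff rates, Hz.}
#'   \item{rate_jitter_cv}{lognormal coefficient of variation of per-sniff
#'     instant rates around the regime mean (0 = deterministic cycles).}
#'   \item{regime_dwell_mean}{length-2 vector (passive, active) of exponential
#'     mean dwell times, s; a zero passive dwell yields an active-only train.}
#'   \item{inhalation_fraction}{fraction of the cycle spent inhaling.}
#'   \item{passive_inhalation_fraction}{as above for the passive regime
#'     (defaults to `inhalation_fraction`).}
#'   \item{exh_coupling_beta}{ms of exhalation prolongation per ms of call.}
#'   \item{exh_noise_sd_ms}{SD of the additive noise on prolonged exhalations.}
#'   \item{call_prob_model}{`"latent_rate"` (rat) or `"bout_state"` (mouse).}
#'   \item{call_prob_mean, call_prob_amp, call_prob_fwhm_s}{latent-rate model:
#'     mean per-sniff call probability in the active regime, fluctuation
#'     amplitude (SD of the smoothed latent), and fluctuation FWHM in
#'     seconds.}
#'   \item{bout_enter_prob, bout_stay_prob, call_prob_in_bout,
#'     call_prob_out_bout}{bout-state model transition/emission parameters.}
#'   \item{call_duration_mean_ms, call_duration_sd_ms, call_duration_min_ms}{
#'     Gaussian call-duration law, ms.}
#'   \item{call_latency_mean_ms, call_latency_sd_ms}{gamma law for the delay
#'     between inhalation offset and ultrasound onset, ms.}
#'   \item{subsyllable_gap_prob}{probability that a call contains brief silent
#'     gaps (each 4-18 ms, at most 2) splitting it into sub-syllables.}
#'   \item{call_freq_band_khz}{length-2 whistle frequency band, kHz.}
#'   \item{snr_db}{call tone power over 18-100 kHz band noise power, dB.}
#'   \item{crosstalk_db}{attenuation of a call on the far microphone, dB
#'     (`-Inf` disables crosstalk).}
#'   \item{audio_sr}{audio sampling rate, Hz (250000 default; 192000 is the
#'     documented fast mode, valid for the rat band).}
#'   \item{pressure_sr}{pressure sampling rate, Hz.}
#'   \item{tubing_tf}{a [tubing_tf()] object distorting the pressure trace.}
#'   \item{truncation_frac}{calls are truncated at this fraction of the
#'     (prolonged) exhalation.}
#'   \item{plateau_frac}{near-zero-flow plateau depth during calls, as a
#'     fraction of the exhalation peak.}
#'   \item{pressure_noise_sd}{additive sensor noise on the pressure trace.}
#'   \item{seed}{default RNG seed used when the generator functions are called
#'     without one.}
#' }
#' @export
generator_config <- function(species = c("rat", "mouse"), ...) {
  species <- match.arg(species)
  cfg <- list(
    species = species,
    passive_rate_mean = 2.0,
    active_rate_mean = 8.0,
    rate_jitter_cv = 0.08,
    regime_dwell_mean = c(passive = 10, active = 10),
    inhalation_fraction = 0.33,
    passive_inhalation_fraction = NULL,
    exh_coupling_beta = 0.85,
    exh_noise_sd_ms = 4,
    call_prob_model = "latent_rate",
    call_prob_mean = 0.30,
    call_prob_amp = 0.15,
    call_prob_fwhm_s = 1.5,
    bout_enter_prob = 0.05,
    bout_stay_prob = 0.85,
    call_prob_in_bout = 0.95,
    call_prob_out_bout = 0.01,
    call_duration_mean_ms = 40,
    call_duration_sd_ms = 15,
    call_duration_min_ms = 6,
    call_latency_mean_ms = 8,
    call_latency_sd_ms = 3,
    subsyllable_gap_prob = 0.35,
    call_freq_band_khz = c(30, 90),
    snr_db = 10,
    crosstalk_db = -20,
    audio_sr = 250000,
    pressure_sr = 1000,
    tubing_tf = tubing_tf(fc_hz = 40, delay_s = 0.004),
    truncation_frac = 0.9,
    plateau_frac = 0.12,
    pressure_noise_sd = 0.01,
    seed = 1L
  )
  if (species == "mouse") {
    cfg$passive_rate_mean <- 3.0
    cfg$inhalation_fraction <- 0.20
    cfg$exh_coupling_beta <- 0.32
    cfg$call_prob_model <- "bout_state"
    cfg$call_duration_mean_ms <- 46
    cfg$call_freq_band_khz <- c(50, 100)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  if (is.null(cfg$passive_inhalation_fraction))
    cfg$passive_inhalation_fraction <- cfg$inhalation_fraction
  validate_generator_config(structure(cfg, class = "usv_generator_config"))
}

validate_generator_config <- function(cfg) {
  if (cfg$passive_rate_mean <= 0 || cfg$active_rate_mean <= 0)
    abort("breathing rates must be > 0")
  if (cfg$inhalation_fraction < 0 || cfg$inhalation_fraction > 1 ||
      cfg$passive_inhalation_fraction < 0 || cfg$passive_inhalation_fraction > 1)
    abort("inhalation fractions must lie in [0, 1]")
  if (cfg$call_duration_mean_ms <= 0 || cfg$call_duration_min_ms <= 0)
    abort("call durations must be > 0")
  if (any(cfg$regime_dwell_mean < 0)) abort("regime dwell means must be >= 0")
  if (cfg$audio_sr < 2000 * cfg$call_freq_band_khz[2])
    abort(sprintf("audio_sr = %g violates Nyquist for a %g kHz call band",
                  cfg$audio_sr, cfg$call_freq_band_khz[2]))
  cfg
}

regime_params <- function(cfg, regime) {
  active <- regime == "active"
  list(rate = ifelse(active, cfg$active_rate_mean, cfg$passive_rate_mean),
       inh_frac = ifelse(active, cfg$inhalation_fraction,
                         cfg$passive_inhalation_fraction))
}

#' Generate a ground-truth sniff train
#'
#' Simulates a two-state (passive/active) semi-Markov breathing process with
#' exponential regime dwell times. Within a regime, per-sniff instant rates
#' are lognormally jittered around the regime mean; each cycle is split into
#' inhalation and exhalation by the regime's inhalation fraction. Landmarks
#' are contiguous: a sniff's exhalation offset is the next inhalation onset.
#'
#' @param config [generator_config()].
#' @param duration session duration, seconds.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return tibble with one row per sniff: `sniff_id`, `t_inh_on`, `t_inh_off`,
#'   `t_exh_off` (s), `regime`, `rate_nominal` (the sampled instant rate, Hz).
#' @export
generate_sniff_train <- function(config, duration, seed = config$seed) {
  stopifnot_scalar_pos(duration, "duration")
  if (!is.null(seed)) set.seed(seed)
  dw <- config$regime_dwell_mean
  if (length(dw) == 1L) dw <- c(passive = dw, active = dw)

  # regime schedule covering the session
  states <- character(0); bounds <- numeric(0)
  t <- 0
  state <- if (dw[1] <= 0) "active" else
    sample(c("passive", "active"), 1L, prob = dw / sum(dw))
  while (t < duration) {
    d <- if (dw[[state]] <= 0) 0 else rexp(1L, 1 / dw[[state]])
    if (d > 0) { states <- c(states, state); bounds <- c(bounds, t); t <- t + d }
    state <- if (state == "active" && dw[["passive"]] > 0) "passive" else "active"
  }

  est_n <- ceiling(duration * config$active_rate_mean * 1.5) + 16L
  on <- numeric(est_n); inh <- numeric(est_n)
  reg <- character(est_n); rate <- numeric(est_n)
  t <- 0; i <- 0L
  sig <- sqrt(log(1 + config$rate_jitter_cv^2))
  while (TRUE) {
    regime <- states[findInterval(t, bounds)]
    rp <- regime_params(config, regime)
    r <- rp$rate * exp(rnorm(1L, -sig^2 / 2, sig))
    cyc <- 1 / r
    if (t + cyc > duration) break
    i <- i + 1L
    if (i > length(on)) {  # grow if jitter produced more sniffs than estimated
      on <- c(on, numeric(est_n)); inh <- c(inh, numeric(est_n))
      reg <- c(reg, character(est_n)); rate <- c(rate, numeric(est_n))
    }
    on[i] <- t; inh[i] <- rp$inh_frac * cyc; reg[i] <- regime; rate[i] <- r
    t <- t + cyc
  }
  if (i == 0L) abort("duration too short for a single sniff cycle")
  on <- on[seq_len(i)]
  exh_off <- c(on[-1], t)
  tibble::tibble(
    sniff_id = seq_len(i),
    t_inh_on = on,
    t_inh_off = on + inh[seq_len(i)],
    t_exh_off = exh_off,
    regime = reg[seq_len(i)],
    rate_nominal = rate[seq_len(i)]
  )
}

# latent per-sniff call probability, by model
latent_call_probability <- function(config, sniffs) {
  n <- nrow(sniffs)
  p <- numeric(n)
  active <- sniffs$regime == "active"
  if (config$call_prob_model == "latent_rate") {
    # smooth latent fluctuation: white noise on a 10 ms grid convolved with a
    # Gaussian kernel of FWHM call_prob_fwhm_s, unit variance, sampled at
    # sniff onsets
    dt <- 0.01
    sigma <- config$call_prob_fwhm_s / (2 * sqrt(2 * log(2))) / dt
    half <- ceiling(3 * sigma)
    kern <- exp(-0.5 * ((-half:half) / sigma)^2)
    kern <- kern / sqrt(sum(kern^2))  # unit-variance output
    ng <- ceiling(max(sniffs$t_exh_off) / dt) + 2L * half + 2L
    z <- stats::filter(rnorm(ng), kern, sides = 2L)
    idx <- pmin(pmax(round(sniffs$t_inh_on / dt) + half + 1L, half + 1L), ng - half)
    zi <- as.numeric(z[idx])
    p[active] <- pmin(pmax(config$call_prob_mean +
                             config$call_prob_amp * zi[active], 0), 0.95)
  } else if (config$call_prob_model == "bout_state") {
    state <- 0L
    pa <- numeric(sum(active))
    for (j in seq_len(sum(active))) {
      state <- if (state == 1L) rbinom(1L, 1L, config$bout_stay_prob)
               else rbinom(1L, 1L, config$bout_enter_prob)
      pa[j] <- if (state == 1L) config$call_prob_in_bout else config$call_prob_out_bout
    }
    p[active] <- pa
  } else abort("unknown call_prob_model")
  p
}

#' Inject ground-truth calls into a sniff train
#'
#' Draws vocal sniffs from the configured call-probability process (active
#' regime only), places each call shortly after its sniff's inhalation
#' offset, and lengthens that exhalation by `exh_coupling_beta` times the
#' call duration (plus noise), shifting all downstream landmarks so cycles
#' never overlap. Calls that would not fit are truncated at
#' `truncation_frac` of the prolonged exhalation and flagged. Optionally,
#' calls are split into sub-syllables by silent gaps shorter than 20 ms;
#' gaps do not change the call's extent.
#'
#' @param sniffs output of [generate_sniff_train()].
#' @param config [generator_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return list with elements `sniffs` (input augmented with `is_vocal`,
#'   `p_call`, call landmarks, all landmark times shifted by accumulated
#'   prolongations), `calls` (one row per vocal sniff: `call_id`, `sniff_id`,
#'   `onset`, `offset`, `duration`, `truncated`), and `emissions` (one row per
#'   sub-syllable: `call_id`, `onset`, `offset`).
#' @export
inject_calls <- function(sniffs, config, seed = config$seed + 1L) {
  if (nrow(sniffs) == 0L) abort("sniff train is empty")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sniffs)
  p <- latent_call_probability(config, sniffs)
  vocal <- rbinom(n, 1L, p) == 1L

  inh_dur <- sniffs$t_inh_off - sniffs$t_inh_on
  exh_dur <- sniffs$t_exh_off - sniffs$t_inh_off
  nv <- sum(vocal)

  dur <- lat <- rep(NA_real_, n)
  truncated <- rep(FALSE, n)
  new_exh <- exh_dur
  if (nv > 0) {
    d <- pmax(rnorm(nv, config$call_duration_mean_ms, config$call_duration_sd_ms),
              config$call_duration_min_ms) / 1000
    shp <- (config$call_latency_mean_ms / config$call_latency_sd_ms)^2
    l <- rgamma(nv, shape = shp,
                scale = config$call_latency_mean_ms / shp) / 1000
    eps <- rnorm(nv, 0, config$exh_noise_sd_ms) / 1000
    base <- exh_dur[vocal]
    beta <- config$exh_coupling_beta
    tf <- config$truncation_frac
    denom <- 1 - tf * beta
    dmax <- if (denom > 0) pmax((tf * (base + eps) - l) / denom,
                                config$call_duration_min_ms / 1000) else Inf
    trunc_v <- d > dmax
    d <- pmin(d, dmax)
    dur[vocal] <- d; lat[vocal] <- l; truncated[vocal] <- trunc_v
    new_exh[vocal] <- pmax(base + beta * d + eps, l + d + 0.002)
  }

  delta <- new_exh - exh_dur
  shift_before <- c(0, cumsum(delta))[seq_len(n)]
  t_on <- sniffs$t_inh_on + shift_before
  t_off <- sniffs$t_inh_off + shift_before
  t_exh <- sniffs$t_exh_off + shift_before + delta

  call_onset <- ifelse(vocal, t_off + lat, NA_real_)
  call_offset <- call_onset + dur

  out_sniffs <- dplyr::mutate(sniffs,
    t_inh_on = t_on, t_inh_off = t_off, t_exh_off = t_exh,
    instant_rate = 1 / (dplyr::lead(t_on) - t_on),
    is_vocal = vocal, p_call = p,
    call_onset = call_onset, call_offset = call_offset,
    call_duration = dur, truncated = truncated)

  calls <- dplyr::filter(out_sniffs, .data$is_vocal)
  calls <- tibble::tibble(
    call_id = seq_len(nrow(calls)),
    sniff_id = calls$sniff_id,
    onset = calls$call_onset,
    offset = calls$call_offset,
    duration = calls$call_duration,
    truncated = calls$truncated
  )
  emissions <- split_subsyllables(calls, config)
  list(sniffs = out_sniffs, calls = calls, emissions = emissions)
}

# split calls into sub-syllable emission segments with silent gaps < 20 ms;
# the call extent (first onset to last offset) is unchanged
split_subsyllables <- function(calls, config) {
  if (nrow(calls) == 0L)
    return(tibble::tibble(call_id = integer(), onset = numeric(), offset = numeric()))
  res <- purrr::map(seq_len(nrow(calls)), function(i) {
    on <- calls$onset[i]; off <- calls$offset[i]
    dur <- off - on
    has_gap <- runif(1L) < config$subsyllable_gap_prob && dur > 0.016
    if (!has_gap)
      return(tibble::tibble(call_id = calls$call_id[i], onset = on, offset = off))
    n_gaps <- if (dur > 0.05 && runif(1L) < 0.4) 2L else 1L
    max_total_gap <- dur - 0.004 * (n_gaps + 1L)
    gd <- runif(n_gaps, 0.004, pmin(0.018, max_total_gap / n_gaps))
    # place gap centers away from the edges, keeping >= 4 ms of emission
    usable <- dur - sum(gd) - 0.004 * (n_gaps + 1L)
    cuts <- sort(runif(n_gaps, 0, max(usable, 0)))
    seg_on <- on
    ons <- numeric(0); offs <- numeric(0)
    pos <- 0.004 + cuts + cumsum(c(0, gd[-n_gaps]))
    for (g in seq_len(n_gaps)) {
      gap_start <- on + pos[g] + (g - 1) * 0.004
      ons <- c(ons, seg_on); offs <- c(offs, gap_start)
      seg_on <- gap_start + gd[g]
    }
    ons <- c(ons, seg_on); offs <- c(offs, off)
    tibble::tibble(call_id = calls$call_id[i], onset = ons, offset = offs)
  })
  dplyr::bind_rows(res)
}
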