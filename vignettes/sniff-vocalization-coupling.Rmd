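---
title: "Methods: sniff-vocalization coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sniff-vocalization coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Rodents emit ultrasonic vocalizations (USVs) — near-pure whistles in the
30-90 kHz range for rats ("50 kHz family") and 50-100 kHz for mice — while
breathing in two distinguishable modes: passive respiration (1-4 Hz) and
active sniffing in the theta range (5-10 Hz). Ultrasound can only be produced
during exhalation, so the respiratory cycle imposes structure on vocal
output: calls begin shortly after the inhalation ends, finish before the
exhalation peaks, and lengthen the exhalation that carries them. `vocalsniff`
implements the full analysis chain for studying this coupling: USV detection
by multitaper spectral entropy, two-microphone caller assignment, intranasal
pressure reconstruction and sniff segmentation, phase warping, coupling
statistics, and surrogate-based bout analysis — plus a synthetic-data
generator that produces paired audio and pressure recordings with exhaustive
ground truth, so every stage can be validated end to end.

# USV detection by spectral entropy

Audio is analyzed with a multitaper sonogram: 2 ms windows, 0.25 ms steps,
1 kHz bandwidth, 3 Slepian tapers (time-bandwidth product 2, tapers
$\le 2NW-1$). For each frame the power vector $P$ over the ultrasonic band
(18-100 kHz, 0.5 kHz bins) is normalized to $P_n = P / \sum P$ and scored by
its Shannon entropy $H = -\sum P_n \log_2 P_n$. A whistle concentrates power
in a few bins (low $H$); broadband noise spreads it (high $H$, near
$\log_2 n_{bins} \approx 7.4$ bits). Frames with $H < 6.5$ bits are
ultrasound candidates; runs separated by gaps of at most 20 ms are merged (so
segments are bounded by silences longer than 20 ms), and segments shorter
than 3 ms are discarded. Segments whose median sonic-band (5-18 kHz) to
ultrasonic power ratio exceeds 1 are rejected as broadband noise; this
automatic rule replaces manual curation of borderline segments.

Two-microphone assignment: segments detected on one channel only belong to
that channel's subject; temporally overlapping segments are compared by
their per-frame peak-frequency tracks — divergence of more than 1 kHz for
more than 3 ms means both subjects called simultaneously (each keeps its own
segment) — and otherwise by mean frame entropy over the overlap, the lower
entropy (cleaner, nearer) channel winning.

Numerical choices: the frame step may be a non-integer number of samples
(62.5 at 250 kHz); frame start indices are rounded per frame so the frame
count is exactly $\lfloor (L - w)/s \rfloor + 1$ and frame times are exact
multiples of the step. The per-frame entropy statistic, not minimum or
maximum, is used for the microphone comparison; the frequency track is the
per-frame argmax of ultrasonic power. The multitaper core is compiled
(Rcpp/Armadillo) and streams in chunks, returning only per-frame features,
so hour-scale 250 kHz recordings fit in memory; the full power matrix is
available on request for short signals.

# Respiration

Intranasal pressure is recorded through tubing that low-passes and delays
the signal. The generator models this as a first-order low-pass (40 Hz
corner) plus a 4 ms delay. `estimate_transfer_function()` recovers the
complex gain by Fourier deconvolution of a broadband reference/distorted
pair (regularized where the reference spectrum falls below 1e-3 of its
maximum), and `correct_tubing_distortion()` inverse-filters recordings,
flooring transfer-function magnitudes below 1e-3 of the maximum to bound
noise amplification. The round trip is exact to well under 1% RMSE in the
0.5-20 Hz sniffing band.

Preprocessing removes slow sensor drift with a zero-phase 0.1 Hz high-pass
(second-order Butterworth), applies the conventional 400 Hz low-pass as an
anti-noise smoother (at a 1 kHz sampling rate a low-pass cannot remove
drift, so the drift filter is separate), z-scores the trace, and flips the
sign so inhalation is positive (raw sensors record inhalation as a pressure
decrease).

Sniff segmentation finds positive-slope crossings of a fixed threshold
(0 SD) for inhalation onsets and the following negative-slope crossings for
inhalation offsets. Crossings are validated by a +-0.05 SD hysteresis band
and located with sub-sample linear interpolation, which is what makes 2 ms
landmark tolerances reachable at a 1 kHz sampling rate. A sniff runs from
its inhalation onset to the next onset (= exhalation offset); cycles with
inhalations under 20 ms are rejected; the trailing incomplete cycle is
dropped. Instant rate is the reciprocal of the onset-to-onset interval.

Phase warping follows the three-point morph: each inhalation is mapped
linearly onto $[0, f]$ and each exhalation onto $[f, 1]$, where $f$ is the
ratio of the population-mean inhalation duration to the population-mean
cycle duration. Phase 0 is inhalation onset, $f$ the inhalation-exhalation
transition (0.33 for the rat preset), and 1 the exhalation offset.

# Coupling statistics

A *call* is the ultrasound emitted within a single sniff, spanning the first
to the last ultrasonic time point; sub-syllable gaps shorter than the
bounding silence do not split it. Events straddling an inhalation onset
(rare, < 1 in 1000 under defaults) are split at the landmark, preserving the
at-most-one-call-per-sniff invariant. *Vocal ratio* is ultrasound coverage
of a 3 s window; *call rate* counts calls per second in the same window;
*ongoing sniff rate* averages instant rates of silent sniffs only. Windows
stride by 0.25 s, and windows without eligible sniffs are gaps, not zeros.
Sniff-rate-conditioned curves use 1 Hz bins over 1-12 Hz, computed per
session. *Instant call rate* is defined only for calls on consecutive
sniffs, as the reciprocal of the inter-onset interval, and is paired with
the instant rate of the immediately preceding silent sniff.

Prolongation regressions are ordinary least squares of per-sniff exhalation
(and, as a control, inhalation) duration on call duration, in ms. The
silence-threshold sweep re-segments the merged ultrasound stream at each
threshold and reports the percentage of resulting "calls" that share a sniff
with no other call and the percentage confined to a single sniff. Silences
are gaps of at least 2 ms. Autocorrelations subtract the segment mean,
normalize by the lag-0 value (constant segments contribute a flat 1), and
average over 3 s segments.

# Bout analysis

Each session yields a binary vector with one element per sniff (1 = vocal).
A bout is a maximal run of ones. Two surrogate ensembles provide nulls: the
*constant* model draws i.i.d. Bernoulli vectors at the observed vocal
fraction; the *variable* model first estimates a local call probability by
convolving the observed vector with a Gaussian kernel whose FWHM is the
"rate estimation window" W (in sniffs; truncated at 3 SD, renormalized at
the edges, clipped to [0, 1]) and then draws element-wise. Bout
probabilities are pooled across the ensemble (1000 surrogates by
convention; the acceptance checks use 200, which leaves Monte-Carlo error
well below the effect sizes involved). The per-length statistic is
$\log_{10} P_{real}(k) / P_{surr}(k)$ for $k = 1..5$; ensemble lengths never
observed receive a 0.5-bout pseudocount so the ratio stays finite. Sweeping
W from 4 to 256 locates the fluctuation timescale that best explains the
observed bout structure: the W minimizing $\sum_k |LLR|$.

# The synthetic-data generator

The generator is first-class, tested code that encodes the statistical
structure the analysis assumes; its defaults are the study conditions for
all acceptance checks.

* **Breathing**: a two-state semi-Markov process (passive 2 Hz / active
  8 Hz regime means, exponential dwell, 10 s each) with per-sniff lognormal
  rate jitter (CV 0.08). This is the simplest process producing the blocked
  alternation seen in respiration spectrograms.
* **Inhalation fraction**: 0.33 of the cycle for the rat preset (0.20
  mouse), applied in both regimes. Giving passive breathing a 0.5 duty
  cycle would drag the population-mean inhalation fraction — and with it
  the warped transition phase — to ~0.40, because passive cycles are four
  times longer; resting rodent breathing in fact spends less than half the
  cycle inspiring. A `passive_inhalation_fraction` field exists for
  sensitivity analyses.
* **Calls**: only in the active regime. The rat preset draws per-sniff call
  probability from a smooth latent process (Gaussian-kernel-smoothed noise,
  FWHM 1.5 s, mean 0.30, SD 0.15, clipped) — the 1-2 s rate-fluctuation
  timescale that bout analysis should recover as W about 12 sniffs at theta
  sniffing. The mouse preset uses a persistent two-state bout process
  (entry 0.05, persistence 0.85, in-bout call probability 0.95), which no
  smoothed-rate Bernoulli null reproduces — the species contrast the bout
  module must resolve. Call durations are Gaussian (40 +- 15 ms rat,
  46 +- 15 ms mouse, 6 ms floor); onset latency after inhalation offset is
  gamma (8 +- 3 ms).
* **Prolongation**: a vocal sniff's exhalation is lengthened by
  `exh_coupling_beta` (0.85 rat, 0.32 mouse) times the call duration plus
  4 ms Gaussian noise; inhalations are untouched; downstream landmarks
  shift so cycles never overlap. Calls that would overrun are truncated at
  90% of the available exhalation and flagged — qualitatively producing the
  call-duration drop at very fast sniffing.
* **Audio**: each call is a smooth random-spline FM whistle within the
  species band, at 10 dB tone-to-band-noise power over white noise, with
  0.5 ms raised-cosine ramps; 35% of calls contain one or two silent gaps
  of 4-18 ms. The far microphone receives a -20 dB copy. Default sampling
  is 250 kHz; 192 kHz is a documented fast mode, valid for the rat band
  (the detector band is then capped at the 96 kHz Nyquist limit).
* **Pressure**: inhalation and exhalation render as half-sine lobes;
  vocal exhalations open with a near-zero-flow plateau (12% of the
  exhalation peak, below the 20% bound) until the call ends. Inhalation
  amplitude is scaled per sniff so inhaled and exhaled areas match (equal
  tidal volume), which keeps the session mean at zero and makes the 0 SD
  segmentation threshold meaningful after z-scoring. The clean trace is
  written in the raw sensor convention (inhalation = decrease) and a
  tubing-distorted copy accompanies it.

What the generator does *not* emulate: vocal-tract acoustics, echoes,
microphone directivity, cage noise transients, animal movement artifacts,
22 kHz alarm calls, or behavioral correlations between subjects. Passing
tests therefore demonstrate the correctness and calibration of the analysis
chain on data obeying its assumptions, not detector performance on any
particular laboratory's recordings.

# Problem sizes and reproducibility

Every stochastic routine takes an explicit seed, and a fixed seed
reproduces sessions bit for bit. The acceptance checks use: five 380 s rat
sessions (about 2100 vocal sniffs) for the rat slope; four 450 s mouse
sessions (about 1300 vocal sniffs) for the mouse slope; 1000-1800 s
ground-truth sessions for the segmentation, instant-rate, and phase checks;
hour-long sniff trains (about 17000 sniffs) with 200 surrogates per window
for the bout-structure contrast. These sizes put the Monte-Carlo standard
error of each recovered quantity a factor of 2-3 below its validation
tolerance, and sessions are simulated and analyzed one at a time so peak
memory stays under ~2 GB even for 250 kHz audio.

# Known limitations

* The entropy detector assumes narrowband calls well above the noise floor;
  at low SNR the 6.5-bit threshold clips call edges before it misses calls
  entirely.
* Caller assignment handles two microphones; larger arrays are out of
  scope.
* The silence-threshold sweep assumes calls much shorter than sniff cycles;
  species with continuous song would violate it.
* The tubing model is linear and time-invariant; a kinked or partially
  blocked cannula is not.
* Statistical inference across sessions/animals (ANOVA and the like) is
  deliberately left to the user: the package computes per-session
  quantities.
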