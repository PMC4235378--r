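# vocalsniff

Tools for analyzing how rodent ultrasonic vocalizations (USVs) are bound to
the respiratory cycle. Rats emit "50 kHz family" calls (30-90 kHz whistles)
almost exclusively during active sniffing (5-10 Hz), and mice behave
similarly in the 50-100 kHz band. Because ultrasound requires exhalation,
the sniff cycle segments vocal output into discrete calls, imposes theta
timing on them, and is itself deformed by them: the exhalation carrying a
call stretches roughly in proportion to the call's duration.

`vocalsniff` is aimed at researchers recording paired ultrasonic audio and
intranasal pressure (or validating methods for such recordings). It
implements:

* **USV detection** by multitaper spectral entropy: a 2 ms / 0.25 ms / 1 kHz
  / 3-taper sonogram; per frame, the power vector `P` over 18-100 kHz is
  normalized and scored by `H = -sum(Pn * log2(Pn))`; runs of frames with
  `H < 6.5` bits, merged across gaps of up to 20 ms and at least 3 ms long,
  are putative calls; segments with high 5-18 kHz (sonic) power are
  discarded as noise.
* **Caller assignment** from two microphones: single-channel detections go
  to that channel's subject; overlapping detections are split by frequency
  tracks diverging >1 kHz for >3 ms (both called) or awarded to the
  lower-entropy channel.
* **Respiration analysis**: Fourier-deconvolution correction of tubing
  distortion, drift removal and z-scoring, threshold-crossing sniff
  segmentation (sub-sample landmarks, <20 ms inhalations rejected), and
  three-point phase warping (inhalation onset = 0, exhalation onset =
  population inhalation fraction, exhalation offset = 1).
* **Coupling statistics**: per-sniff call linkage (a call is the ultrasound
  within one sniff), vocal ratio and call rate in 3 s windows, exhalation
  and inhalation prolongation regressions against call duration, call
  onset/offset phase distributions, warped mean waveforms, silence-threshold
  segmentation sweeps, instant call rate on consecutive sniffs, and
  segment-averaged autocorrelations.
* **Bout analysis**: bout-length distributions of vocal-sniff runs compared
  against constant-probability and Gaussian-smoothed variable-probability
  surrogate ensembles via per-length `log10` likelihood ratios, swept over
  rate-estimation windows of 4-256 sniffs.
* **A synthetic-data generator** producing two-channel ultrasonic audio and
  tubing-distorted pressure traces with complete ground truth (sniff
  landmarks, call times, latent call probabilities), used to calibrate and
  validate every stage.

## Worked example

Simulate a two-minute rat session, detect its calls from the audio, segment
sniffs from the pressure trace, and measure the coupling:

```r
library(vocalsniff)

cfg   <- generator_config("rat", audio_sr = 192000)   # 192 kHz fast mode
ses   <- simulate_session(cfg, duration = 120, n_subjects = 1, seed = 7)
calls <- detect_calls(ses$audio, params = spectrogram_params(freq_hi = 96))

trace  <- ses$subjects[[1]]$pressure$raw |>
  correct_tubing_distortion(1000, cfg$tubing_tf) |>
  preprocess_pressure(1000)
sniffs <- segment_sniffs(trace, 1000)
linked <- link_calls_to_sniffs(sniffs, calls)

fit <- prolongation_regression(linked)
fit
#> Sniff prolongation regression (145 vocal sniffs)
#>   exhalation: slope 0.874 ms/ms (R^2 0.77)
#>   inhalation: slope 0.011 ms/ms (R^2 0.00)

phase_locking(linked, trace = trace)
#> Phase locking over 145 vocal sniffs (exhalation onset at phase 0.319)
#>   median onset phase  0.358
#>   median offset phase 0.594

evaluate_against_truth(calls, ses$subjects[[1]]$calls)[c("recall", "precision")]
#> $recall    [1] 1
#> $precision [1] 1
```

The exhalation slope says each millisecond of ultrasound stretches the
exhalation by ~0.87 ms (the generator injected 0.85; the inhalation control
stays at 0). Call onsets cluster just after the inhalation-exhalation
transition (phase 0.32) and end before the exhalation peak — the phase
locking that lets a 20-60 ms silence threshold reproduce sniff-cycle call
segmentation without any pressure recording. `glance()`/`tidy()` give the
regressions as tibbles; `autoplot()` methods cover phase distributions,
silence sweeps, and bout likelihood ratios. `run_pipeline()` chains all
stages from a session or an on-disk manifest and writes CSVs plus a JSON
summary; `inst/cli/vocalsniff.R` wraps simulate/detect/sniff/run/bouts for
shell use.

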