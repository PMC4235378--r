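mk_sniffs <- function(on, inh = 0.04) {
  n <- length(on) - 1L
  tibble::tibble(
    sniff_id = seq_len(n),
    t_inh_on = on[-length(on)],
    t_inh_off = on[-length(on)] + inh,
    t_exh_off = on[-1],
    inh_duration = inh,
    exh_duration = on[-1] - on[-length(on)] - inh,
    duration = on[-1] - on[-length(on)],
    instant_rate = 1 / (on[-1] - on[-length(on)]))
}

test_that("linking pools within-sniff ultrasound into one call", {
  sn <- mk_sniffs(seq(0, 1.25, by = 0.125))
  # one 40 ms emission inside the first exhalation
  ev <- tibble::tibble(onset = 0.05, offset = 0.09)
  li <- link_calls_to_sniffs(sn, ev)
  expect_identical(sum(li$is_vocal), 1L)
  expect_equal(li$call_duration[1], 0.04)
  # two 10 ms emissions with an 8 ms gap -> one call spanning 28 ms
  ev2 <- tibble::tibble(onset = c(0.05, 0.068), offset = c(0.06, 0.078))
  li2 <- link_calls_to_sniffs(sn, ev2)
  expect_identical(sum(li2$is_vocal), 1L)
  expect_equal(li2$call_duration[1], 0.028)
  # silent sniffs flagged FALSE
  expect_true(all(!li2$is_vocal[-1]))
  # event crossing an inhalation onset is split between both sniffs
  ev3 <- tibble::tibble(onset = 0.10, offset = 0.15)
  li3 <- link_calls_to_sniffs(sn, ev3)
  expect_identical(sum(li3$is_vocal), 2L)
  expect_equal(li3$call_offset[1], 0.125)
  expect_equal(li3$call_onset[2], 0.125)
  # orphan: before the first sniff
  ev4 <- tibble::tibble(onset = -0.5, offset = -0.45)
  li4 <- link_calls_to_sniffs(sn, ev4)
  expect_identical(attr(li4, "n_orphans"), 1L)
  expect_true(all(!li4$is_vocal))
})

test_that("vocal ratio is coverage per window", {
  # no ultrasound
  expect_equal(vocal_ratio(tibble::tibble(onset = numeric(), offset = numeric()),
                           t_range = c(0, 3))$vocal_ratio, 0)
  # 75 ms in a 3 s window -> 0.025
  ev <- tibble::tibble(onset = 1, offset = 1.075)
  vr <- vocal_ratio(ev, window = 3, stride = 3, t_range = c(0, 3))
  expect_equal(vr$vocal_ratio[1], 0.025)
  # full coverage -> 1
  ev2 <- tibble::tibble(onset = 0, offset = 3)
  expect_equal(vocal_ratio(ev2, window = 3, stride = 3,
                           t_range = c(0, 3))$vocal_ratio[1], 1)
  expect_true(all(vr$vocal_ratio >= 0 & vr$vocal_ratio <= 1))
})

test_that("phase locking puts a call starting at inhalation offset at the transition", {
  sn <- mk_sniffs(seq(0, 1.25, by = 0.125))
  ev <- tibble::tibble(onset = 0.04, offset = 0.09)  # onset == t_inh_off
  li <- link_calls_to_sniffs(sn, ev)
  pl <- phase_locking(li, mean_inh_frac = 0.33)
  expect_equal(pl$phases$onset_phase, 0.33)
  expect_lt(pl$phases$offset_phase, 1)
  expect_error(phase_locking(link_calls_to_sniffs(sn, ev[0, ])), "no vocal")
})

test_that("prolongation regression recovers injected coupling on a full session", {
  cfg <- generator_config("rat")
  st <- generate_sniff_train(cfg, 900, seed = 30)
  tr <- inject_calls(st, cfg, seed = 31)
  pz <- synthesize_pressure(tr, cfg, 900)
  pp <- preprocess_pressure(correct_tubing_distortion(pz$raw, 1000, cfg$tubing_tf), 1000)
  sn <- segment_sniffs(pp, 1000)
  li <- link_calls_to_sniffs(sn, tr$emissions)
  fit <- prolongation_regression(li)
  g <- glance(fit)
  expect_lt(abs(g$slope[g$response == "exhalation"] - 0.85), 0.05)
  expect_lt(abs(g$slope[g$response == "inhalation"]), 0.05)
  td <- tidy(fit)
  expect_identical(nrow(td), 4L)
  # calling lowers the instantaneous rate relative to the preceding silent sniff
  ok <- stats::complete.cases(fit$rates)
  expect_lt(mean(fit$rates$vocal_rate[ok]),
            mean(fit$rates$preceding_silent_rate[ok]))
  # subtracting the call duration recovers the underlying rhythm
  expect_gt(mean(fit$rates$corrected_rate[ok]),
            mean(fit$rates$vocal_rate[ok]))
  expect_error(prolongation_regression(li[0, ]), "vocal sniffs")
})

test_that("silence classes and segmentation sweep behave as constructed", {
  sn <- mk_sniffs(seq(0, 2.5, by = 0.125))
  # calls on sniffs 1 and 2, the first split by an 8 ms sub-syllable gap
  ev <- tibble::tibble(onset = c(0.050, 0.068, 0.175),
                       offset = c(0.060, 0.080, 0.215))
  sil <- silence_durations(ev)
  expect_equal(sil$duration_ms, c(8, 95), tolerance = 1e-9)
  expect_identical(sil$class, c("short", "long"))
  sw <- silence_segmentation_sweep(ev, sn, thresholds_ms = c(3, 40, 3000))
  # 3 ms threshold splits the sub-syllables -> two "calls" share sniff 1
  expect_identical(sw$n_calls[1], 3L)
  expect_lt(sw$pct_unique_per_sniff[1], 95)
  # 40 ms: both calls unique and contained
  expect_identical(sw$n_calls[2], 2L)
  expect_equal(sw$pct_unique_per_sniff[2], 100)
  expect_equal(sw$pct_not_spanning[2], 100)
  # absurd threshold merges across sniffs -> spanning
  expect_identical(sw$n_calls[3], 1L)
  expect_lt(sw$pct_not_spanning[3], 95)
})

test_that("instant call rate uses consecutive sniffs only", {
  sn <- mk_sniffs(seq(0, 1.0, by = 0.125))
  sn$is_vocal <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  sn$call_onset <- ifelse(sn$is_vocal, sn$t_inh_on + 0.045, NA)
  sn$call_offset <- sn$call_onset + 0.04
  sn$call_duration <- ifelse(sn$is_vocal, 0.04, NA)
  icr <- instant_call_rate(sn)
  # only the first pair (sniffs 1,2) is consecutive: onsets 160 ms apart -> 6.25 Hz?
  expect_identical(nrow(icr), 1L)
  expect_equal(icr$instant_call_rate, 1 / 0.125)
  # preceding silent sniff rate: none before sniff 1
  expect_true(is.na(icr$preceding_silent_rate))
})

test_that("rate-conditioned metrics bin correctly and leave gaps", {
  cfg <- generator_config("rat")
  st <- generate_sniff_train(cfg, 400, seed = 33)
  tr <- inject_calls(st, cfg, seed = 34)
  rcm <- rate_conditioned_metrics(tr$sniffs)
  expect_true(all(rcm$binned$pct_vocal >= 0 & rcm$binned$pct_vocal <= 100,
                  na.rm = TRUE))
  expect_true(all(rcm$binned$call_rate >= 0, na.rm = TRUE))
  # vocal output concentrates at fast sniffing (peak bin in the active band)
  pk <- rcm$binned$sniff_rate[which.max(rcm$binned$pct_vocal)]
  expect_gte(pk, 5)
  # instant call rate correlates positively with the preceding silent rate
  inst <- rcm$instant[stats::complete.cases(rcm$instant), ]
  expect_gt(cor(inst$instant_call_rate, inst$preceding_silent_rate), 0)
})

test_that("autocorrelation: periodic, constant, and white series", {
  # 7 Hz periodic pulse train -> first side peak at ~143 ms
  dt <- 0.001
  tt <- seq(0, 30, by = dt)
  x <- as.numeric((tt %% (1 / 7)) < 0.04)
  ac <- usv_autocorrelation(x, dt, max_lag = 0.3)
  side <- ac[ac$lag > 0.08, ]
  expect_equal(side$lag[which.max(side$acf)], 1 / 7, tolerance = 0.01)
  # constant series -> flat 1
  acc <- usv_autocorrelation(rep(2, 9000), dt, max_lag = 0.2)
  expect_true(all(acc$acf == 1))
  # white noise -> side lobes near zero
  set.seed(40)
  acw <- usv_autocorrelation(rnorm(30000), dt, max_lag = 0.2)
  expect_lt(max(abs(acw$acf[acw$lag > 0])), 0.1)
  expect_equal(acw$acf[1], 1)
})

test_that("vocal/silent warped waveforms separate during the call window", {
  cfg <- generator_config("rat")
  ses <- simulate_session(cfg, duration = 200, n_subjects = 1, seed = 41,
                          audio = FALSE)
  tr <- ses$subjects[[1]]
  pp <- preprocess_pressure(
    correct_tubing_distortion(tr$pressure$raw, 1000, cfg$tubing_tf), 1000)
  sn <- segment_sniffs(pp, 1000)
  li <- link_calls_to_sniffs(sn, tr$emissions)
  pl <- phase_locking(li, trace = pp, sr = 1000)
  expect_s3_class(pl, "usv_phase_locking")
  wf <- tidyr::pivot_wider(pl$waveforms, names_from = "vocal",
                           values_from = "pressure")
  mid <- wf$phase > pl$mean_inh_frac + 0.05 & wf$phase < 0.6
  # vocal exhalation shows the near-zero plateau, silent the deep trough
  expect_gt(mean(wf$`TRUE`[mid]), mean(wf$`FALSE`[mid]))
  # onset phases sit after the inhalation-exhalation transition
  expect_gt(median(pl$phases$onset_phase), pl$mean_inh_frac)
  expect_lt(median(pl$phases$offset_phase), 1)
})
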