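test_that("transfer-function estimation: identity, delay, analytic low-pass", {
  sr <- 1000
  ref <- flat_broadband(60000, seed = 20)
  # identity
  tf0 <- estimate_transfer_function(ref, ref, sr)
  band <- tf0$freq_hz > 0.5 & tf0$freq_hz < 450
  expect_lt(max(abs(Mod(tf0$gain[band]) - 1)), 1e-4)
  expect_lt(max(abs(Arg(tf0$gain[band]))), 1e-4)
  # pure 5 ms delay -> linear phase with slope -2*pi*0.005
  del <- apply_transfer_function(ref, sr, tubing_tf(fc_hz = Inf, delay_s = 0.005))
  tfd <- estimate_transfer_function(ref, del, sr)
  f <- tfd$freq_hz[tfd$freq_hz > 1 & tfd$freq_hz < 50]
  ph <- Arg(tfd$gain[tfd$freq_hz > 1 & tfd$freq_hz < 50])
  slope <- coef(lm(ph ~ f))[[2]]
  expect_equal(-slope / (2 * pi), 0.005, tolerance = 0.01)
  # discrete first-order low-pass vs analytic RC magnitude, 0.5-20 Hz
  fc <- 15
  a <- exp(-2 * pi * fc / sr)
  dist <- as.numeric(signal::filter(signal::Arma(b = 1 - a, a = c(1, -a)), ref))
  tfl <- estimate_transfer_function(ref, dist, sr)
  sel <- tfl$freq_hz >= 0.5 & tfl$freq_hz <= 20
  analytic <- 1 / sqrt(1 + (tfl$freq_hz[sel] / fc)^2)
  expect_lt(max(abs(Mod(tfl$gain[sel]) - analytic) / analytic), 0.02)
  expect_error(estimate_transfer_function(ref, ref[-1], sr), "equal length")
})

test_that("tubing correction round trip is exact within the sniffing band", {
  cfg <- generator_config("rat")
  st <- generate_sniff_train(cfg, 60, seed = 21)
  tr <- inject_calls(st, cfg, seed = 22)
  pz <- synthesize_pressure(tr, cfg, 60)
  rec <- correct_tubing_distortion(pz$raw, 1000, cfg$tubing_tf)
  bp <- signal::butter(3, c(0.5, 20) / 500, type = "pass")
  r1 <- signal::filtfilt(bp, rec)
  r0 <- signal::filtfilt(bp, pz$clean)
  rmse <- sqrt(mean((r1 - r0)^2))
  expect_lt(rmse / sd(r0), 0.01)
  # identity transfer function leaves the trace untouched
  x2 <- correct_tubing_distortion(pz$clean, 1000, identity_tf())
  expect_equal(x2, pz$clean, tolerance = 1e-9)
  # pure-gain (x2) transfer function: inversion halves the amplitude
  gain2 <- structure(list(type = "tabulated", freq_hz = c(0, 500),
                          gain = c(2 + 0i, 2 + 0i)),
                     class = "usv_transfer_function")
  halved <- correct_tubing_distortion(pz$clean, 1000, gain2)
  expect_equal(halved, pz$clean / 2, tolerance = 1e-9)
})

test_that("corrected landmarks match the clean-trace segmentation within 2 ms", {
  cfg <- generator_config("rat")
  st <- generate_sniff_train(cfg, 120, seed = 23)
  tr <- inject_calls(st, cfg, seed = 24)
  pz <- synthesize_pressure(tr, cfg, 120)
  sn_clean <- segment_sniffs(preprocess_pressure(pz$clean, 1000), 1000)
  rec <- correct_tubing_distortion(pz$raw, 1000, cfg$tubing_tf)
  sn_rec <- segment_sniffs(preprocess_pressure(rec, 1000), 1000)
  expect_equal(nrow(sn_rec), nrow(sn_clean), tolerance = 0.01)
  m <- vapply(sn_clean$t_inh_on,
              function(t) min(abs(sn_rec$t_inh_on - t)), numeric(1))
  expect_lt(median(m), 0.002)
  expect_gte(mean(m < 0.002), 0.99)
})

test_that("preprocessing normalizes, fixes the sign, and shrugs off drift", {
  cfg <- generator_config("rat")
  st <- generate_sniff_train(cfg, 60, seed = 25)
  tr <- inject_calls(st, cfg, seed = 26)
  pz <- synthesize_pressure(tr, cfg, 60)
  pp <- preprocess_pressure(pz$clean, 1000)
  expect_lt(abs(mean(pp)), 1e-9)
  expect_lt(abs(sd(pp) - 1), 1e-9)
  # raw inhalation deflections are negative; preprocessed ones positive
  s1 <- tr$sniffs[2, ]
  ii <- round(s1$t_inh_on * 1000 + 8):round(s1$t_inh_off * 1000 - 5)
  expect_true(all(pp[ii] > 0))
  # 5-SD linear drift leaves landmarks within 2 ms
  drift <- seq(0, 5 * sd(pz$clean), length.out = length(pz$clean))
  ppd <- preprocess_pressure(pz$clean + drift, 1000)
  sn0 <- segment_sniffs(pp, 1000)
  snd <- segment_sniffs(ppd, 1000)
  m <- vapply(sn0$t_inh_on, function(t) min(abs(snd$t_inh_on - t)), numeric(1))
  expect_gte(mean(m < 0.002), 0.99)
  expect_error(preprocess_pressure(rep(1, 5000), 1000), "zero variance")
  expect_error(preprocess_pressure(rnorm(500), 1000), "2 s")
})

test_that("sinusoid segmentation yields textbook landmarks", {
  sr <- 1000
  t <- (0:19999) / sr
  x <- sin(2 * pi * 8 * t)
  attr(x, "sr") <- sr
  sn <- segment_sniffs(x, sr, threshold = 0)
  expect_equal(unique(round(1000 * (sn$t_exh_off - sn$t_inh_on), 1)), 125.0)
  expect_equal(unique(round(1000 * sn$inh_duration, 1)), 62.5)
  expect_equal(sn$instant_rate, rep(8, nrow(sn)), tolerance = 1e-3)
  # no crossings -> empty
  flatline <- rep(0.01, 5000); attr(flatline, "sr") <- sr
  expect_identical(nrow(segment_sniffs(flatline, sr)), 0L)
})

test_that("cycles with sub-20 ms inhalations are rejected", {
  sr <- 1000
  # construct: normal sniff, then one with a 15 ms inhalation, then normal
  mk <- function(ti, te) c(sin(pi * seq(0, 1, length.out = ti)) ,
                           -sin(pi * seq(0, 1, length.out = te))[-1])
  x <- c(rep(-0.2, 50), mk(60, 60), mk(15, 90), mk(60, 60), mk(60, 60),
         rep(-0.2, 50))
  attr(x, "sr") <- sr
  sn <- segment_sniffs(x, sr)
  # four cycles: the last has no following onset, the 15 ms one is aberrant
  expect_identical(nrow(sn), 2L)
  expect_true(all(sn$inh_duration >= 0.020))
})

test_that("segmentation equals the sample-scan crossing oracle", {
  for (seed in 1:8) {
    x <- make_smooth_trace(4000, seed = seed)
    want <- oracle_crossings(x, 1000)
    got <- vocalsniff:::threshold_crossings(x, 1000)
    expect_equal(got$up, want$up, tolerance = 1e-12)
    expect_equal(got$down, want$down, tolerance = 1e-12)
  }
})

test_that("sniff phase is the three-point piecewise-linear warp", {
  # landmarks: onset 0, inh offset 40 ms, exh offset 160 ms
  expect_equal(sniff_phase(0, 0, 0.04, 0.16, 0.33), 0)
  expect_equal(sniff_phase(0.04, 0, 0.04, 0.16, 0.33), 0.33)
  expect_equal(sniff_phase(0.16, 0, 0.04, 0.16, 0.33), 1)
  expect_equal(sniff_phase(0.02, 0, 0.04, 0.16, 0.33), 0.5 * 0.33)
  # monotone within the sniff
  tt <- seq(0, 0.16, by = 0.001)
  ph <- sniff_phase(tt, 0, 0.04, 0.16, 0.4)
  expect_true(all(diff(ph) > 0))
  expect_error(sniff_phase(0.2, 0, 0.04, 0.16, 0.33), "outside")
})

test_that("ongoing sniff rate averages only eligible sniffs per window", {
  sn <- tibble::tibble(
    t_inh_on = c(0.2, 0.5, 0.8, 1.1),
    instant_rate = c(8, 8, 6, 7),
    is_vocal = c(FALSE, FALSE, FALSE, TRUE))
  r <- ongoing_sniff_rate(sn, window = 3, stride = 3, t_range = c(0, 3))
  expect_equal(r$sniff_rate[1], mean(c(8, 8, 6)))
  # vocal-only window -> gap
  snv <- dplyr::mutate(sn, is_vocal = TRUE)
  rv <- ongoing_sniff_rate(snv, window = 3, stride = 3, t_range = c(0, 3))
  expect_true(is.na(rv$sniff_rate[1]))
  # silent_only off includes everything
  ra <- ongoing_sniff_rate(sn, window = 3, stride = 3, silent_only = FALSE,
                           t_range = c(0, 3))
  expect_equal(ra$sniff_rate[1], mean(c(8, 8, 6, 7)))
})
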