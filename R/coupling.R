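#' Link ultrasound events to sniff cycles
#'
#' Pools all ultrasound emitted within one sniff (inhalation onset to
#' exhalation offset) into a single call spanning the first to the last
#' ultrasound time point; this is the physiologically grounded definition of
#' a "call". An event straddling an inhalation onset is split at that
#' landmark into per-sniff parts. Events falling outside every sniff are
#' counted as orphans and excluded.
#'
#' @param sniffs sniff table ([segment_sniffs()] or generator ground truth).
#' @param events tibble of ultrasound intervals with `onset`/`offset`
#'   (detected segments or ground-truth emissions).
#' @return the sniff table augmented with `is_vocal`, `call_onset`,
#'   `call_offset`, `call_duration`; attribute `n_orphans` counts excluded
#'   events.
#' @export
link_calls_to_sniffs <- function(sniffs, events) {
  sn <- sniffs
  n <- nrow(sn)
  pieces_on <- numeric(0); pieces_off <- numeric(0); pieces_sniff <- integer(0)
  orphans <- 0L
  if (nrow(events)) {
    ev <- events[order(events$onset), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      a <- ev$onset[i]; b <- ev$offset[i]
      while (b - a > 1e-9) {
        j <- findInterval(a, sn$t_inh_on)
        if (j < 1L || a >= sn$t_exh_off[j]) {
          # starts in a gap (rejected sniff or before the first one): skip to
          # the next sniff onset if the event reaches it, else orphan
          nxt <- if (j < n) sn$t_inh_on[j + 1L] else Inf
          if (b > nxt) { a <- nxt; next }
          orphans <- orphans + 1L
          break
        }
        e <- min(b, sn$t_exh_off[j])
        pieces_on <- c(pieces_on, a); pieces_off <- c(pieces_off, e)
        pieces_sniff <- c(pieces_sniff, j)
        a <- e
      }
    }
  }
  call_on <- rep(NA_real_, n); call_off <- rep(NA_real_, n)
  if (length(pieces_sniff)) {
    agg_on <- tapply(pieces_on, pieces_sniff, min)
    agg_off <- tapply(pieces_off, pieces_sniff, max)
    ids <- as.integer(names(agg_on))
    call_on[ids] <- as.numeric(agg_on)
    call_off[ids] <- as.numeric(agg_off)
  }
  out <- dplyr::mutate(sn,
    is_vocal = !is.na(call_on),
    call_onset = call_on,
    call_offset = call_off,
    call_duration = call_off - call_on)
  attr(out, "n_orphans") <- orphans
  out
}

#' Vocal ratio: fraction of time spent producing ultrasound
#'
#' Computed in sliding windows as the total ultrasound time overlapping the
#' window divided by the window length; it requires no call segmentation.
#'
#' @param events ultrasound intervals (`onset`/`offset`).
#' @param window window length, s (3 s convention).
#' @param stride window stride, s.
#' @param t_range length-2 time range to cover; defaults to the event span.
#' @return tibble: `time` (window center), `vocal_ratio` in `[0, 1]`.
#' @export
vocal_ratio <- function(events, window = 3, stride = 0.25, t_range = NULL) {
  merged <- merge_intervals(events)
  t_range <- t_range %||% (if (nrow(merged)) range(merged$onset, merged$offset)
                           else c(0, window))
  centers <- seq(t_range[1] + window / 2,
                 max(t_range[2] - window / 2, t_range[1] + window / 2),
                 by = stride)
  cov <- interval_coverage(merged, centers - window / 2, centers + window / 2)
  tibble::tibble(time = centers, vocal_ratio = cov / window)
}

#' Phase locking of ultrasound to the sniff cycle
#'
#' Warps every sniff to the common three-point phase axis ([sniff_phase()])
#' and returns the distribution of call onset and offset phases, plus (when a
#' pressure trace is supplied) the mean warped waveform of vocal and silent
#' sniffs.
#'
#' @param linked output of [link_calls_to_sniffs()].
#' @param mean_inh_frac population inhalation fraction; computed from
#'   `linked` when `NULL`.
#' @param trace optional preprocessed pressure trace for mean waveforms.
#' @param sr trace sampling rate (attribute used when missing).
#' @param n_phase number of phase samples for the warped waveforms.
#' @return object of class `usv_phase_locking`: list with `phases` (tibble:
#'   `sniff_id`, `onset_phase`, `offset_phase`), `waveforms` (tibble: `phase`,
#'   `vocal`, `pressure`; `NULL` without a trace) and `mean_inh_frac`.
#' @export
phase_locking <- function(linked, mean_inh_frac = NULL, trace = NULL,
                          sr = NULL, n_phase = 100) {
  if (!any(linked$is_vocal)) abort("no vocal sniffs; phase locking undefined")
  mean_inh_frac <- mean_inh_frac %||% mean_inhalation_fraction(linked)
  voc <- dplyr::filter(linked, .data$is_vocal)
  phases <- tibble::tibble(
    sniff_id = voc$sniff_id,
    onset_phase = sniff_phase(voc$call_onset, voc$t_inh_on, voc$t_inh_off,
                              voc$t_exh_off, mean_inh_frac),
    offset_phase = sniff_phase(voc$call_offset, voc$t_inh_on, voc$t_inh_off,
                               voc$t_exh_off, mean_inh_frac))
  waveforms <- NULL
  if (!is.null(trace)) {
    sr <- sr %||% attr(trace, "sr")
    if (is.null(sr)) abort("`sr` must be supplied with `trace`")
    ph <- seq(0, 1, length.out = n_phase)
    n_inh <- sum(ph <= mean_inh_frac)
    warp_one <- function(on, off, exh) {
      t_inh <- seq(on, off, length.out = n_inh)
      t_exh <- seq(off, exh, length.out = n_phase - n_inh + 1L)[-1L]
      tt <- c(t_inh, t_exh)
      approx(seq_along(trace) / sr, as.numeric(trace), tt, rule = 2)$y
    }
    acc <- list(vocal = 0, silent = 0); cnt <- c(vocal = 0L, silent = 0L)
    for (k in seq_len(nrow(linked))) {
      w <- warp_one(linked$t_inh_on[k], linked$t_inh_off[k], linked$t_exh_off[k])
      key <- if (linked$is_vocal[k]) "vocal" else "silent"
      acc[[key]] <- acc[[key]] + w
      cnt[[key]] <- cnt[[key]] + 1L
    }
    waveforms <- dplyr::bind_rows(
      tibble::tibble(phase = ph, vocal = TRUE,
                     pressure = if (cnt[["vocal"]]) acc$vocal / cnt[["vocal"]] else NA_real_),
      tibble::tibble(phase = ph, vocal = FALSE,
                     pressure = if (cnt[["silent"]]) acc$silent / cnt[["silent"]] else NA_real_))
  }
  structure(list(phases = phases, waveforms = waveforms,
                 mean_inh_frac = mean_inh_frac),
            class = "usv_phase_locking")
}

#' Regression of sniff-phase durations on call duration
#'
#' Ordinary least squares of exhalation duration (and, as a control,
#' inhalation duration) on the duration of the ultrasound emitted within the
#' sniff, across vocal sniffs. A slope near 1 means exhalations stretch
#' one-for-one with vocalization; inhalation slopes near 0 indicate the
#' inhalation is untouched. Also summarizes the instantaneous-rate cost of
#' calling: the vocal sniff's rate, the preceding silent sniff's rate, and
#' the rate recomputed after subtracting the call duration from the vocal
#' sniff's period.
#'
#' @param linked output of [link_calls_to_sniffs()] with durations present.
#' @param min_vocal minimum number of vocal sniffs required.
#' @return object of class `usv_prolongation_fit` with elements `exh`, `inh`
#'   (lm fits on ms scales), `rates` (tibble) and `n_vocal`. Supports
#'   [tidy()] and [glance()].
#' @export
prolongation_regression <- function(linked, min_vocal = 10L) {
  voc <- dplyr::filter(linked, .data$is_vocal, !is.na(.data$call_duration))
  if (nrow(voc) < min_vocal)
    abort(sprintf("need >= %d vocal sniffs, got %d", min_vocal, nrow(voc)))
  dat <- tibble::tibble(
    call_ms = voc$call_duration * 1000,
    exh_ms = voc$exh_duration * 1000,
    inh_ms = voc$inh_duration * 1000)
  if (var(dat$call_ms) == 0) abort("degenerate call-duration variance")
  fit_exh <- lm(exh_ms ~ call_ms, data = dat)
  fit_inh <- lm(inh_ms ~ call_ms, data = dat)

  # instantaneous-rate comparison around vocal sniffs
  prev_silent_rate <- rep(NA_real_, nrow(linked))
  last_silent <- NA_real_
  for (k in seq_len(nrow(linked))) {
    prev_silent_rate[k] <- last_silent
    if (!linked$is_vocal[k] && is.finite(linked$instant_rate[k]))
      last_silent <- linked$instant_rate[k]
  }
  vi <- which(linked$is_vocal)
  rates <- tibble::tibble(
    vocal_rate = linked$instant_rate[vi],
    preceding_silent_rate = prev_silent_rate[vi],
    corrected_rate = 1 / (linked$duration[vi] - linked$call_duration[vi]))
  structure(list(exh = fit_exh, inh = fit_inh, rates = rates,
                 n_vocal = nrow(voc)),
            class = "usv_prolongation_fit")
}

#' Silence durations in the ultrasound stream
#'
#' Gaps of at least `min_ms` between successive ultrasound intervals,
#' classified as short (< 20 ms, within-sniff), long (> 60 ms, spanning at
#' least one inhalation) or intermediate.
#'
#' @param events ultrasound intervals.
#' @param min_ms minimum gap counted as a silence, ms.
#' @return tibble: `start`, `end`, `duration_ms`, `class`.
#' @export
silence_durations <- function(events, min_ms = 2) {
  merged <- merge_intervals(events)
  if (nrow(merged) < 2L)
    return(tibble::tibble(start = numeric(), end = numeric(),
                          duration_ms = numeric(), class = character()))
  st <- merged$offset[-nrow(merged)]
  en <- merged$onset[-1L]
  dur <- (en - st) * 1000
  keep <- dur >= min_ms
  tibble::tibble(start = st[keep], end = en[keep], duration_ms = dur[keep],
                 class = dplyr::case_when(dur[keep] < 20 ~ "short",
                                          dur[keep] > 60 ~ "long",
                                          TRUE ~ "intermediate"))
}

#' Silence-threshold call segmentation vs. sniff-cycle segmentation
#'
#' For each silence-duration threshold, ultrasound separated by silences at
#' least that long is merged into "calls"; each call is then compared with
#' the sniff landmarks. Reported are the percentage of calls that share a
#' sniff with no other call and the percentage that do not span more than one
#' sniff: both high means silence segmentation reproduces the sniff-cycle
#' segmentation.
#'
#' @param events ultrasound intervals.
#' @param sniffs sniff table.
#' @param thresholds_ms silence thresholds to sweep, ms.
#' @param min_silence_ms gaps shorter than this never split (2 ms).
#' @return tibble of class `usv_silence_sweep`: `threshold_ms`, `n_calls`,
#'   `pct_unique_per_sniff`, `pct_not_spanning`; the silence histogram input
#'   is attached as attribute `silences`.
#' @export
silence_segmentation_sweep <- function(events, sniffs,
                                       thresholds_ms = c(seq(2, 100, 2),
                                                         seq(110, 300, 10)),
                                       min_silence_ms = 2) {
  merged <- merge_intervals(events)
  sil <- silence_durations(events, min_ms = min_silence_ms)
  res <- purrr::map_dfr(thresholds_ms, function(th) {
    if (nrow(merged) == 0L)
      return(tibble::tibble(threshold_ms = th, n_calls = 0L,
                            pct_unique_per_sniff = NA_real_,
                            pct_not_spanning = NA_real_))
    gaps <- (merged$onset[-1L] - merged$offset[-nrow(merged)]) * 1000
    brk <- gaps >= pmax(th, min_silence_ms)
    grp <- cumsum(c(1L, as.integer(brk)))
    call_on <- merged$onset[!duplicated(grp)]
    call_off <- merged$offset[rev(!duplicated(rev(grp)))]
    j_on <- sniff_index_of(call_on, sniffs)
    j_off <- sniff_index_of(pmax(call_on, call_off - 1e-9), sniffs)
    found <- !is.na(j_on)
    spans <- is.na(j_off) | (j_off != j_on)
    # neighbors only: calls are time-ordered and disjoint
    lo <- ifelse(is.na(j_on), NA, j_on)
    hi <- ifelse(is.na(j_off), lo, j_off)
    share_next <- hi[-length(hi)] >= lo[-1L]
    shares <- c(share_next, FALSE) | c(FALSE, share_next)
    tibble::tibble(
      threshold_ms = th, n_calls = length(call_on),
      pct_unique_per_sniff = 100 * mean(!shares[found], na.rm = TRUE),
      pct_not_spanning = 100 * mean(!spans[found]))
  })
  attr(res, "silences") <- sil
  class(res) <- c("usv_silence_sweep", class(res))
  res
}

# index of the sniff whose [inh_on, exh_off) interval contains t; NA if none
sniff_index_of <- function(t, sniffs) {
  j <- findInterval(t, sniffs$t_inh_on)
  j[j < 1L] <- NA_integer_
  bad <- !is.na(j) & t >= sniffs$t_exh_off[pmax(j, 1L)]
  j[bad] <- NA_integer_
  j
}

#' Instant call rate for calls on consecutive sniffs
#'
#' The reciprocal of the interval between the onsets of calls emitted in two
#' consecutive sniff cycles, paired with the instant rate of the immediately
#' preceding silent sniff. Calls separated by one or more silent sniffs are
#' excluded.
#'
#' @param linked output of [link_calls_to_sniffs()].
#' @return tibble: `time` (first call onset), `instant_call_rate` (Hz),
#'   `preceding_silent_rate` (Hz, `NA` when no silent sniff precedes).
#' @export
instant_call_rate <- function(linked) {
  vi <- which(linked$is_vocal)
  if (length(vi) < 2L)
    return(tibble::tibble(time = numeric(), instant_call_rate = numeric(),
                          preceding_silent_rate = numeric()))
  prev_silent_rate <- rep(NA_real_, nrow(linked))
  last_silent <- NA_real_
  for (k in seq_len(nrow(linked))) {
    prev_silent_rate[k] <- last_silent
    if (!linked$is_vocal[k] && is.finite(linked$instant_rate[k]))
      last_silent <- linked$instant_rate[k]
  }
  consec <- vi[which(diff(vi) == 1L)]
  # also require temporal contiguity (no rejected sniff in between)
  contig <- abs(linked$t_exh_off[consec] - linked$t_inh_on[consec + 1L]) < 1e-6
  consec <- consec[contig]
  tibble::tibble(
    time = linked$call_onset[consec],
    instant_call_rate = 1 / (linked$call_onset[consec + 1L] -
                               linked$call_onset[consec]),
    preceding_silent_rate = prev_silent_rate[consec])
}

#' Call metrics conditioned on the ongoing sniff rate
#'
#' Windowed call rate, percentage of vocal sniffs and mean call duration are
#' joined to the ongoing (silent-sniff) rate in the same window and then
#' averaged in 1 Hz sniff-rate bins; empty bins are gaps, not zeros.
#'
#' @param linked output of [link_calls_to_sniffs()].
#' @param window,stride sliding-window parameters, s.
#' @param rate_breaks sniff-rate bin edges, Hz.
#' @return object of class `usv_rate_metrics`: list with `windowed` (per
#'   window: `time`, `sniff_rate`, `call_rate`, `pct_vocal`,
#'   `mean_call_duration_ms`), `binned` (per rate bin) and `instant`
#'   ([instant_call_rate()] output).
#' @export
rate_conditioned_metrics <- function(linked, window = 3, stride = 0.25,
                                     rate_breaks = seq(0.5, 12.5, 1)) {
  rate <- ongoing_sniff_rate(linked, window, stride, silent_only = TRUE)
  win <- purrr::map_dfr(rate$time, function(ct) {
    inw <- linked$t_inh_on >= ct - window / 2 & linked$t_inh_on < ct + window / 2
    nv <- sum(linked$is_vocal[inw])
    tibble::tibble(
      time = ct,
      call_rate = nv / window,
      pct_vocal = if (any(inw)) 100 * nv / sum(inw) else NA_real_,
      mean_call_duration_ms =
        if (nv) 1000 * mean(linked$call_duration[inw & linked$is_vocal]) else NA_real_)
  })
  windowed <- dplyr::left_join(rate, win, by = "time")
  mids <- (rate_breaks[-1] + rate_breaks[-length(rate_breaks)]) / 2
  binned <- windowed |>
    dplyr::filter(!is.na(.data$sniff_rate)) |>
    dplyr::mutate(bin = cut(.data$sniff_rate, rate_breaks, labels = FALSE)) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      sniff_rate = mids[.data$bin[1]],
      call_rate = mean(.data$call_rate, na.rm = TRUE),
      pct_vocal = mean(.data$pct_vocal, na.rm = TRUE),
      mean_call_duration_ms = mean(.data$mean_call_duration_ms, na.rm = TRUE),
      n_windows = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"bin")
  structure(list(windowed = windowed, binned = binned,
                 instant = instant_call_rate(linked)),
            class = "usv_rate_metrics")
}

#' Segment-averaged autocorrelation
#'
#' Splits a regularly sampled series into fixed-length segments, computes the
#' mean-subtracted autocorrelation of each (normalized by its lag-0 value;
#' constant segments contribute a flat autocorrelation of 1), and averages
#' across segments. Used both for binary ultrasound-presence series against
#' pressure traces and for vocal-ratio against sniff-rate series.
#'
#' @param x numeric series, regularly sampled.
#' @param dt sample interval, s.
#' @param max_lag maximum lag, s.
#' @param segment segment length, s.
#' @return tibble: `lag` (s), `acf`.
#' @export
usv_autocorrelation <- function(x, dt, max_lag = 0.5, segment = 3) {
  seg_n <- max(2L, round(segment / dt))
  lag_n <- min(round(max_lag / dt), seg_n - 1L)
  n_seg <- floor(length(x) / seg_n)
  if (n_seg < 1L) abort("series shorter than one segment")
  acc <- numeric(lag_n + 1L)
  for (s in seq_len(n_seg)) {
    y <- x[((s - 1L) * seg_n + 1L):(s * seg_n)]
    y <- y - mean(y)
    if (sum(y^2) == 0) {
      acc <- acc + 1
    } else {
      a <- stats::acf(y, lag.max = lag_n, plot = FALSE, demean = FALSE)$acf[, 1, 1]
      acc <- acc + a
    }
  }
  tibble::tibble(lag = (0:lag_n) * dt, acf = acc / n_seg)
}

#' Binary ultrasound-presence series from emission intervals
#'
#' @param events ultrasound intervals.
#' @param dt sample interval, s.
#' @param t_range length-2 range to cover.
#' @return numeric 0/1 vector sampled every `dt`.
#' @export
emissions_to_binary <- function(events, dt = 0.001, t_range = NULL) {
  merged <- merge_intervals(events)
  t_range <- t_range %||% c(0, max(merged$offset, 0))
  tt <- seq(t_range[1], t_range[2], by = dt)
  j <- findInterval(tt, merged$onset)
  as.numeric(j >= 1L & tt < merged$offset[pmax(j, 1L)])
}
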