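#' Run the full analysis pipeline on a session
#'
#' Chains the stages: USV detection on each audio channel (entropy detector +
#' caller assignment), tubing correction and preprocessing of each pressure
#' trace, sniff segmentation, call-sniff linkage, coupling statistics
#' (prolongation regressions, phase locking, vocal ratio, silence sweep,
#' rate-conditioned metrics) and surrogate bout analysis. Results are written
#' as CSV files plus a machine-readable JSON summary; a parameter log records
#' everything actually used. A stage failure aborts with a stage-tagged error,
#' leaving earlier outputs in place.
#'
#' @param session a `usv_session` (in-memory) or path to a `manifest.json`.
#' @param out_dir output directory.
#' @param params [spectrogram_params()].
#' @param tf transfer function used to undo tubing distortion; defaults to the
#'   session/manifest tubing parameters; `NULL` skips correction.
#' @param n_surrogates surrogate ensemble size for the bout stage.
#' @param bout_windows rate-estimation windows for the bout stage.
#' @param seed seed for the surrogate ensembles.
#' @return (invisibly) a list with per-subject results and the summary; files
#'   under `out_dir`.
#' @export
run_pipeline <- function(session, out_dir, params = spectrogram_params(),
                         tf = NULL, n_surrogates = 200,
                         bout_windows = c(4, 8, 12, 16, 32, 64, 128, 256),
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("[stage %s] %s", name, conditionMessage(e))))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.character(session)) {
    m <- stage("manifest", read_manifest(session))
    channels <- stage("read_audio", purrr::map(m$audio, read_wav))
    pressures <- stage("read_pressure", purrr::map(m$pressure, read_pressure_csv))
    if (is.null(tf) && !is.null(m$tubing_tf))
      tf <- tubing_tf(m$tubing_tf$fc_hz, m$tubing_tf$delay_s)
    cfg_for_log <- m
  } else {
    channels <- session$audio
    pressures <- purrr::map(session$subjects, "pressure") |>
      purrr::map(function(p) list(samples = p$raw, sr = p$sr))
    if (is.null(tf)) tf <- session$config$tubing_tf
    cfg_for_log <- session$config
  }
  n_sub <- length(pressures)

  events <- stage("detect", {
    if (is.null(channels) || !length(channels)) NULL
    else detect_calls(channels, params = params, subjects = seq_len(n_sub))
  })

  results <- purrr::map(seq_len(n_sub), function(s) {
    pr <- pressures[[s]]
    corrected <- stage("tubing_correction", {
      if (is.null(tf)) pr$samples
      else correct_tubing_distortion(pr$samples, pr$sr, tf)
    })
    trace <- stage("preprocess", preprocess_pressure(corrected, pr$sr))
    sniffs <- stage("segment_sniffs", segment_sniffs(trace, pr$sr))
    ev <- if (!is.null(events)) dplyr::filter(events, .data$subject == s)
          else tibble::tibble(onset = numeric(), offset = numeric())
    linked <- stage("link", link_calls_to_sniffs(sniffs, ev))
    coupling <- stage("coupling", {
      if (sum(linked$is_vocal) >= 10) {
        fit <- prolongation_regression(linked)
        pl <- phase_locking(linked, trace = trace, sr = pr$sr)
        rcm <- rate_conditioned_metrics(linked)
        sweep <- silence_segmentation_sweep(ev, linked)
        list(fit = fit, phase = pl, rate_metrics = rcm, sweep = sweep)
      } else NULL
    })
    bouts <- stage("bouts", {
      if (sum(linked$is_vocal) >= 5)
        llr_window_sweep(as.integer(linked$is_vocal), windows = bout_windows,
                         n_surrogates = n_surrogates,
                         seed = seed_from(seed, 100 + s))
      else NULL
    })
    list(sniffs = linked, events = ev, coupling = coupling, bouts = bouts)
  })

  stage("write", {
    for (s in seq_len(n_sub)) {
      r <- results[[s]]
      write.csv(format_times(
        dplyr::select(r$sniffs, -dplyr::any_of(c("freq_track")))),
        file.path(out_dir, sprintf("sniffs_s%d.csv", s)), row.names = FALSE)
      if (nrow(r$events))
        write.csv(format_times(dplyr::select(r$events, -dplyr::any_of("freq_track"))),
                  file.path(out_dir, sprintf("calls_s%d.csv", s)), row.names = FALSE)
      if (!is.null(r$coupling)) {
        write.csv(format_times(r$coupling$rate_metrics$windowed),
                  file.path(out_dir, sprintf("metrics_s%d.csv", s)), row.names = FALSE)
        write.csv(as.data.frame(r$coupling$sweep),
                  file.path(out_dir, sprintf("silence_sweep_s%d.csv", s)),
                  row.names = FALSE)
      }
      if (!is.null(r$bouts))
        write.csv(as.data.frame(r$bouts),
                  file.path(out_dir, sprintf("bout_llr_s%d.csv", s)), row.names = FALSE)
    }
  })

  summary <- stage("summary", pipeline_summary(results, params, cfg_for_log, seed))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(results = results, summary = summary))
}

pipeline_summary <- function(results, params, cfg, seed) {
  per_subject <- purrr::imap(results, function(r, s) {
    out <- list(
      n_sniffs = nrow(r$sniffs),
      n_vocal_sniffs = sum(r$sniffs$is_vocal),
      n_detected_events = nrow(r$events),
      pct_vocal_sniffs = if (nrow(r$sniffs))
        100 * mean(r$sniffs$is_vocal) else NA_real_)
    if (!is.null(r$coupling)) {
      g <- glance(r$coupling$fit)
      out$exh_slope_ms_per_ms <- g$slope[g$response == "exhalation"]
      out$inh_slope_ms_per_ms <- g$slope[g$response == "inhalation"]
      out$exh_r_squared <- g$r.squared[g$response == "exhalation"]
      out$median_onset_phase <- median(r$coupling$phase$phases$onset_phase)
      out$median_offset_phase <- median(r$coupling$phase$phases$offset_phase)
      out$mean_inh_frac <- r$coupling$phase$mean_inh_frac
      icr <- r$coupling$rate_metrics$instant$instant_call_rate
      out$instant_call_rate_mode_hz <- if (length(icr)) hist_mode(icr, 0.5) else NA_real_
      sw <- r$coupling$sweep
      i40 <- which.min(abs(sw$threshold_ms - 40))
      out$pct_unique_at_40ms <- sw$pct_unique_per_sniff[i40]
      out$pct_not_spanning_at_40ms <- sw$pct_not_spanning[i40]
    }
    if (!is.null(r$bouts)) {
      agg <- dplyr::summarise(
        dplyr::group_by(dplyr::filter(r$bouts, .data$model == "variable"), .data$W),
        sum_abs_llr = sum(abs(.data$llr[is.finite(.data$llr)])), .groups = "drop")
      out$best_rate_window_sniffs <- agg$W[which.min(agg$sum_abs_llr)]
    }
    out
  })
  list(package_version = as.character(packageVersion("vocalsniff")),
       seed = seed,
       config_hash = config_hash(list(params = unclass(params), cfg = cfg)),
       spectrogram_params = unclass(params),
       subjects = per_subject)
}

# mode of a histogram with fixed-width bins anchored at 0
hist_mode <- function(x, binwidth) {
  b <- floor(x / binwidth)
  tb <- table(b)
  (as.numeric(names(tb)[which.max(tb)]) + 0.5) * binwidth
}

#' Score detections against generator ground truth
#'
#' Matches detected call events to true calls by temporal overlap (the
#' intersection must cover at least `min_overlap` of the longer of the two
#' intervals), greedily in onset order, and reports recall, precision, onset
#' and offset timing errors, and subject-assignment accuracy.
#'
#' @param detected tibble with `onset`, `offset` and optionally `subject`.
#' @param truth tibble of true calls with `onset`, `offset` and optionally
#'   `subject`.
#' @param min_overlap minimum overlap fraction for a match.
#' @return list: `recall`, `precision`, `n_matched`, `median_onset_error_s`,
#'   `median_offset_error_s`, `assignment_accuracy` (`NA` without subjects).
#' @export
evaluate_against_truth <- function(detected, truth, min_overlap = 0.5) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0L) abort("ground truth contains no calls")
  if (nd == 0L)
    return(list(recall = 0, precision = NA_real_, n_matched = 0L,
                median_onset_error_s = NA_real_, median_offset_error_s = NA_real_,
                assignment_accuracy = NA_real_))
  det <- detected[order(detected$onset), , drop = FALSE]
  tru <- truth[order(truth$onset), , drop = FALSE]
  used <- rep(FALSE, nd)
  match_d <- rep(NA_integer_, nt)
  for (i in seq_len(nt)) {
    cand <- which(!used & det$onset < tru$offset[i] & det$offset > tru$onset[i])
    if (!length(cand)) next
    ovl <- pmin(det$offset[cand], tru$offset[i]) - pmax(det$onset[cand], tru$onset[i])
    frac <- ovl / pmax(det$offset[cand] - det$onset[cand],
                       tru$offset[i] - tru$onset[i])
    j <- which.max(frac)
    if (frac[j] >= min_overlap) {
      match_d[i] <- cand[j]
      used[cand[j]] <- TRUE
    }
  }
  ok <- !is.na(match_d)
  acc <- NA_real_
  if ("subject" %in% names(det) && "subject" %in% names(tru) && any(ok))
    acc <- mean(det$subject[match_d[ok]] == tru$subject[ok])
  list(recall = mean(ok),
       precision = sum(ok) / nd,
       n_matched = sum(ok),
       median_onset_error_s = if (any(ok))
         median(abs(det$onset[match_d[ok]] - tru$onset[ok])) else NA_real_,
       median_offset_error_s = if (any(ok))
         median(abs(det$offset[match_d[ok]] - tru$offset[ok])) else NA_real_,
       assignment_accuracy = acc)
}
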