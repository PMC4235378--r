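#' Detect putative USV segments from spectral frames
#'
#' Finds runs of frames whose ultrasonic spectral entropy falls below a fixed
#' threshold, merges runs separated by gaps no longer than `bounding_silence`
#' (so that accepted segments are bounded by longer silences), and discards
#' segments whose extent is below `min_dur`. Segment boundaries are the first
#' and last below-threshold frame times.
#'
#' @param frames output of [compute_spectrogram()].
#' @param entropy_threshold bits; frames below it count as ultrasound.
#' @param min_dur minimum segment extent, s.
#' @param bounding_silence gaps longer than this split segments, s.
#' @return tibble: `segment_id`, `onset`, `offset`, `duration`,
#'   `mean_entropy`, `sonic_ratio` (median over frames of sonic/ultrasonic
#'   power), plus list-columns `frame_time` and `freq_track` (kHz per frame).
#' @export
detect_usv_segments <- function(frames, entropy_threshold = 6.5,
                                min_dur = 0.003, bounding_silence = 0.020) {
  empty <- tibble::tibble(segment_id = integer(), onset = numeric(),
                          offset = numeric(), duration = numeric(),
                          mean_entropy = numeric(), sonic_ratio = numeric(),
                          frame_time = list(), freq_track = list())
  if (nrow(frames) == 0L) return(empty)
  below <- !is.na(frames$entropy) & frames$entropy < entropy_threshold
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_i <- which(r$values)
  run_on <- frames$time[starts[run_i]]
  run_off <- frames$time[ends[run_i]]
  # merge runs separated by gaps <= bounding_silence
  if (length(run_i) > 1L) {
    gap <- run_on[-1L] - run_off[-length(run_off)]
    grp <- cumsum(c(1L, as.integer(gap > bounding_silence)))
  } else grp <- 1L
  first_of <- !duplicated(grp)
  last_of <- rev(!duplicated(rev(grp)))
  seg_on <- run_on[first_of]
  seg_off <- run_off[last_of]
  keep <- (seg_off - seg_on) >= min_dur
  if (!any(keep)) return(empty)
  # below-threshold frame indices per segment, straight from the run table
  run_groups <- split(seq_along(run_i), factor(grp, levels = unique(grp)))[keep]
  segs <- purrr::map(run_groups, function(rr) {
    idx <- unlist(purrr::map(rr, function(k) seq(starts[run_i[k]], ends[run_i[k]])))
    tibble::tibble(
      mean_entropy = mean(frames$entropy[idx]),
      sonic_ratio = median(frames$sonic_power[idx] /
                             pmax(frames$ultra_power[idx], .Machine$double.xmin)),
      frame_time = list(frames$time[idx]),
      freq_track = list(frames$peak_freq[idx]))
  })
  seg_on <- seg_on[keep]; seg_off <- seg_off[keep]
  dplyr::bind_cols(
    tibble::tibble(segment_id = seq_along(seg_on),
                   onset = as.numeric(seg_on), offset = as.numeric(seg_off),
                   duration = as.numeric(seg_off - seg_on)),
    dplyr::bind_rows(segs))
}

#' Discard broadband (sonic-contaminated) segments
#'
#' Narrowband whistles carry essentially no power in the 5-18 kHz sonic band;
#' mechanical noise is broadband. A segment is discarded when its median
#' sonic-to-ultrasonic power ratio exceeds `sonic_ratio_max`.
#'
#' @param segments output of [detect_usv_segments()].
#' @param sonic_ratio_max maximum tolerated ratio (default 1).
#' @return the retained segments.
#' @export
reject_sonic_noise <- function(segments, sonic_ratio_max = 1.0) {
  dplyr::filter(segments, .data$sonic_ratio <= sonic_ratio_max)
}

#' Assign detected segments to the emitting subject
#'
#' Compares time-aligned segment lists from the two microphones. A segment
#' detected on only one channel is assigned to that channel's subject
#' (`single_mic`). When segments overlap in time, their frequency tracks are
#' compared: if they differ by more than `freq_divergence` for longer than
#' `divergence_dur`, both subjects vocalized simultaneously and each receives
#' its own call (`dual_caller`); otherwise the call goes to the channel with
#' the lower mean entropy over the overlap (`entropy_compare`).
#'
#' @param segments_a,segments_b segment tables from channels A and B.
#' @param subjects length-2 subject identifiers.
#' @param freq_divergence kHz difference marking distinct simultaneous calls.
#' @param divergence_dur minimum duration of the divergence, s.
#' @return tibble of call events: `subject`, `onset`, `offset`, `duration`,
#'   `assignment_mode`, `mean_entropy`, `freq_track` (list-column).
#' @export
assign_caller <- function(segments_a, segments_b, subjects = c(1L, 2L),
                          freq_divergence = 1, divergence_dur = 0.003) {
  if (length(subjects) != 2L) abort("exactly two subjects/channels are supported")
  seg_event <- function(seg, subj, mode) {
    tibble::tibble(subject = subj, onset = seg$onset, offset = seg$offset,
                   duration = seg$offset - seg$onset, assignment_mode = mode,
                   mean_entropy = seg$mean_entropy,
                   freq_track = seg$freq_track)
  }
  na <- nrow(segments_a); nb <- nrow(segments_b)
  if (na == 0L && nb == 0L)
    return(seg_event(segments_a[0, ], integer(0), character(0)))
  used_b <- rep(FALSE, nb)
  events <- list()
  for (i in seq_len(na)) {
    a <- segments_a[i, ]
    ov <- which(!used_b & segments_b$onset < a$offset & segments_b$offset > a$onset)
    if (!length(ov)) {
      events[[length(events) + 1L]] <- seg_event(a, subjects[1], "single_mic")
      next
    }
    # best-overlapping partner
    ovl <- pmin(segments_b$offset[ov], a$offset) - pmax(segments_b$onset[ov], a$onset)
    j <- ov[which.max(ovl)]
    used_b[j] <- TRUE
    b <- segments_b[j, ]
    ta <- a$frame_time[[1]]; fa <- a$freq_track[[1]]
    tb <- b$frame_time[[1]]; fb <- b$freq_track[[1]]
    common <- intersect(round(ta * 1e6), round(tb * 1e6))
    div_time <- 0
    if (length(common) > 1L) {
      ia <- match(common, round(ta * 1e6)); ib <- match(common, round(tb * 1e6))
      dstep <- median(diff(sort(common))) / 1e6
      div_time <- sum(abs(fa[ia] - fb[ib]) > freq_divergence) * dstep
    }
    if (div_time > divergence_dur) {
      events[[length(events) + 1L]] <- seg_event(a, subjects[1], "dual_caller")
      events[[length(events) + 1L]] <- seg_event(b, subjects[2], "dual_caller")
    } else if (a$mean_entropy <= b$mean_entropy) {
      events[[length(events) + 1L]] <- seg_event(a, subjects[1], "entropy_compare")
    } else {
      events[[length(events) + 1L]] <- seg_event(b, subjects[2], "entropy_compare")
    }
  }
  for (j in which(!used_b))
    events[[length(events) + 1L]] <- seg_event(segments_b[j, ], subjects[2],
                                               "single_mic")
  out <- dplyr::bind_rows(events)
  dplyr::arrange(out, .data$onset)
}

#' Detect and assign ultrasonic vocalizations in session audio
#'
#' Convenience wrapper chaining [compute_spectrogram()],
#' [detect_usv_segments()], [reject_sonic_noise()] and (for two channels)
#' [assign_caller()].
#'
#' @param channels list of audio channels (`list(samples, sr)`), one per
#'   subject.
#' @param params [spectrogram_params()].
#' @param entropy_threshold,min_dur,bounding_silence see
#'   [detect_usv_segments()].
#' @param sonic_ratio_max see [reject_sonic_noise()].
#' @param subjects subject ids, one per channel.
#' @return tibble of call events as from [assign_caller()]; single-channel
#'   input yields all-`single_mic` events.
#' @export
detect_calls <- function(channels, params = spectrogram_params(),
                         entropy_threshold = 6.5, min_dur = 0.003,
                         bounding_silence = 0.020, sonic_ratio_max = 1.0,
                         subjects = seq_along(channels)) {
  if (length(channels) > 2L) abort("more than two channels is unsupported")
  segs <- purrr::map(channels, function(ch) {
    fr <- compute_spectrogram(ch, params = params)
    reject_sonic_noise(
      detect_usv_segments(fr, entropy_threshold, min_dur, bounding_silence),
      sonic_ratio_max)
  })
  if (length(channels) == 1L) {
    s <- segs[[1]]
    return(tibble::tibble(subject = rep(subjects[1], nrow(s)),
                          onset = s$onset, offset = s$offset,
                          duration = s$duration,
                          assignment_mode = rep("single_mic", nrow(s)),
                          mean_entropy = s$mean_entropy,
                          freq_track = s$freq_track))
  }
  assign_caller(segs[[1]], segs[[2]], subjects = subjects)
}
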