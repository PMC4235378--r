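#' Plot call onset/offset phase distributions and warped waveforms
#'
#' @param object a `usv_phase_locking`.
#' @param bins histogram bins over phase.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot usv_phase_locking
autoplot.usv_phase_locking <- function(object, bins = 40, ...) {
  ph <- tidyr::pivot_longer(object$phases, c("onset_phase", "offset_phase"),
                            names_to = "event", values_to = "phase")
  p <- ggplot2::ggplot(ph, ggplot2::aes(x = .data$phase, fill = .data$event)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6,
                            boundary = 0) +
    ggplot2::geom_vline(xintercept = object$mean_inh_frac, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(onset_phase = "black",
                                          offset_phase = "grey60")) +
    ggplot2::labs(x = "sniff phase (0 = inhalation onset, 1 = exhalation offset)",
                  y = "calls",
                  title = "Ultrasound onset/offset phase within the sniff cycle") +
    ggplot2::theme_minimal()
  p
}

#' Plot mean warped vocal vs silent sniff waveforms
#'
#' @param x a `usv_phase_locking` computed with a pressure trace.
#' @return a ggplot.
#' @export
plot_warped_waveforms <- function(x) {
  if (is.null(x$waveforms)) abort("no waveforms; rerun phase_locking() with a trace")
  ggplot2::ggplot(x$waveforms,
                  ggplot2::aes(x = .data$phase, y = .data$pressure,
                               color = .data$vocal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x$mean_inh_frac, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "red", `FALSE` = "blue"),
                                labels = c(`TRUE` = "vocal", `FALSE` = "silent")) +
    ggplot2::labs(x = "sniff phase", y = "pressure (SD, inhalation positive)",
                  color = NULL, title = "Mean warped sniff waveforms") +
    ggplot2::theme_minimal()
}

#' Plot the silence-threshold segmentation sweep
#'
#' @param object a `usv_silence_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot usv_silence_sweep
autoplot.usv_silence_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("pct_unique_per_sniff", "pct_not_spanning"),
                              names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold_ms, y = .data$pct,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 95, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(
      values = c(pct_unique_per_sniff = "darkorange", pct_not_spanning = "darkgreen"),
      labels = c(pct_unique_per_sniff = "calls not sharing a sniff",
                 pct_not_spanning = "calls within one sniff")) +
    ggplot2::labs(x = "silence threshold (ms)", y = "% of segmented calls",
                  color = NULL,
                  title = "Silence segmentation vs sniff-cycle segmentation") +
    ggplot2::theme_minimal()
}

#' Plot log-likelihood ratios of bout lengths across rate windows
#'
#' @param object a `usv_bout_llr` from [llr_window_sweep()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot usv_bout_llr
autoplot.usv_bout_llr <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$model == "variable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$W, y = .data$llr,
                                   color = factor(.data$length))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_x_log10(breaks = unique(df$W)) +
    ggplot2::labs(x = "rate estimation window (sniffs)",
                  y = "log10 P(real) / P(surrogate)", color = "bout length",
                  title = "Bout-length likelihood ratio vs surrogate models") +
    ggplot2::theme_minimal()
}

#' Overview plot of a pressure trace with call events
#'
#' @param trace preprocessed pressure trace (inhalation positive).
#' @param sr sampling rate, Hz.
#' @param events ultrasound intervals to mark.
#' @param t_range time range to show, s.
#' @return a ggplot.
#' @export
plot_session_trace <- function(trace, sr = NULL, events = NULL,
                               t_range = c(0, 10)) {
  sr <- sr %||% attr(trace, "sr")
  idx <- seq(max(1L, floor(t_range[1] * sr)), min(length(trace),
                                                  ceiling(t_range[2] * sr)))
  df <- tibble::tibble(time = idx / sr, pressure = as.numeric(trace)[idx])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$pressure)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "pressure (SD, inhalation positive)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    ev <- dplyr::filter(events, .data$offset > t_range[1], .data$onset < t_range[2])
    if (nrow(ev))
      p <- p + ggplot2::annotate("rect", xmin = ev$onset, xmax = ev$offset,
                                 ymin = max(df$pressure) * 1.02,
                                 ymax = max(df$pressure) * 1.12,
                                 fill = "red")
  }
  p
}
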