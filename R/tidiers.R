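#' @exportS3Method generics::tidy usv_prolongation_fit
tidy.usv_prolongation_fit <- function(x, ...) {
  one <- function(fit, resp) {
    cf <- summary(fit)$coefficients
    tibble::tibble(response = resp,
                   term = c("intercept_ms", "slope_ms_per_ms"),
                   estimate = cf[, 1], std.error = cf[, 2],
                   statistic = cf[, 3], p.value = cf[, 4])
  }
  dplyr::bind_rows(one(x$exh, "exhalation"), one(x$inh, "inhalation"))
}

#' @exportS3Method generics::glance usv_prolongation_fit
glance.usv_prolongation_fit <- function(x, ...) {
  one <- function(fit, resp) {
    s <- summary(fit)
    tibble::tibble(response = resp,
                   slope = coef(fit)[2], intercept = coef(fit)[1],
                   r.squared = s$r.squared, sigma = s$sigma,
                   nobs = length(fit$residuals))
  }
  dplyr::bind_rows(one(x$exh, "exhalation"), one(x$inh, "inhalation"))
}

#' @export
print.usv_prolongation_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Sniff prolongation regression (%d vocal sniffs)\n", x$n_vocal))
  cat(sprintf("  exhalation: slope %.3f ms/ms (R^2 %.2f)\n",
              g$slope[1], g$r.squared[1]))
  cat(sprintf("  inhalation: slope %.3f ms/ms (R^2 %.2f)\n",
              g$slope[2], g$r.squared[2]))
  invisible(x)
}

#' @export
print.usv_phase_locking <- function(x, ...) {
  cat(sprintf("Phase locking over %d vocal sniffs (exhalation onset at phase %.3f)\n",
              nrow(x$phases), x$mean_inh_frac))
  cat(sprintf("  median onset phase  %.3f\n  median offset phase %.3f\n",
              median(x$phases$onset_phase), median(x$phases$offset_phase)))
  invisible(x)
}

#' @export
print.usv_generator_config <- function(x, ...) {
  cat(sprintf("Synthetic session config (%s preset)\n", x$species))
  cat(sprintf("  breathing: passive %.1f Hz / active %.1f Hz, dwell %s s\n",
              x$passive_rate_mean, x$active_rate_mean,
              paste(x$regime_dwell_mean, collapse = "/")))
  cat(sprintf("  calls: %s model, duration %g +- %g ms, beta %.2f ms/ms, band %g-%g kHz\n",
              x$call_prob_model, x$call_duration_mean_ms, x$call_duration_sd_ms,
              x$exh_coupling_beta, x$call_freq_band_khz[1], x$call_freq_band_khz[2]))
  invisible(x)
}

#' @export
print.usv_surrogate_ensemble <- function(x, ...) {
  cat(sprintf("%s-probability surrogate ensemble: %d surrogates, %d pooled bouts\n",
              x$model, x$n_surrogates, x$n_bouts))
  if (x$model == "variable") cat(sprintf("  rate estimation window W = %g sniffs\n", x$W))
  invisible(x)
}
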