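#' Extract call bouts from a vocal-sniff vector
#'
#' A bout is a maximal stretch of consecutive vocal sniffs (a run of ones in
#' the per-sniff binary vector).
#'
#' @param v binary vector (0/1 or logical), one element per sniff.
#' @return integer vector of bout lengths, in order of occurrence.
#' @export
extract_bouts <- function(v) {
  if (!length(v)) abort("vocal-sniff vector is empty")
  v <- as.integer(as.logical(v))
  r <- rle(v)
  as.integer(r$lengths[r$values == 1L])
}

#' Bout-length distribution
#'
#' @param lengths integer bout lengths (or a binary vector, from which bouts
#'   are extracted).
#' @return tibble: `length`, `count`, `prob` (probabilities sum to 1 over
#'   observed lengths).
#' @export
bout_distribution <- function(lengths) {
  if (is.logical(lengths) || any(lengths == 0L)) lengths <- extract_bouts(lengths)
  if (!length(lengths))
    return(tibble::tibble(length = integer(), count = integer(), prob = numeric()))
  tb <- table(factor(lengths, levels = seq_len(max(lengths))))
  tibble::tibble(length = seq_len(max(lengths)), count = as.integer(tb),
                 prob = as.integer(tb) / sum(tb))
}

# pooled bout counts over a batch of surrogate vectors: rows are flattened
# with a 0 separator so runs never cross vectors
pooled_bout_counts <- function(mat) {
  flat <- as.vector(rbind(t(mat), 0L))
  r <- rle(flat)
  len <- r$lengths[r$values == 1L]
  if (!length(len)) return(integer(0))
  tabulate(len)
}

#' Constant-probability surrogate ensemble
#'
#' Generates binary vectors of the same length as the data where each sniff
#' is vocal independently with the data's overall vocal fraction, and pools
#' bout counts across the ensemble. This is the null model of calls emitted
#' at a constant rate.
#'
#' @param v observed binary vocal-sniff vector.
#' @param n_surrogates ensemble size (1000 by convention).
#' @param seed RNG seed.
#' @return object of class `usv_surrogate_ensemble`: list with `model`,
#'   `n_surrogates`, `p` (constant probability or per-sniff vector),
#'   `counts` (tibble `length`, `count`, `prob` pooled over the ensemble),
#'   `n_bouts`.
#' @export
constant_probability_surrogates <- function(v, n_surrogates = 1000, seed = 1L) {
  v <- as.integer(as.logical(v))
  if (!length(v)) abort("vector is empty")
  p <- mean(v)
  if (p == 0 || p == 1)
    warn(sprintf("degenerate vocal fraction p = %g; surrogates are trivial", p))
  make_surrogate_ensemble(rep(p, length(v)), n_surrogates, seed,
                          model = "constant", p_store = p)
}

#' Variable-probability surrogate ensemble
#'
#' Estimates a local call-production probability by convolving the observed
#' binary vector with a Gaussian kernel whose full width at half maximum is
#' the "rate estimation window" `W` (in sniffs; kernel truncated at 3 SD and
#' renormalized at the edges, values clipped to `[0, 1]`), then draws
#' surrogate vectors element-wise from those probabilities. Small `W` tracks
#' fast rate fluctuations; `W` at or beyond the vector length degenerates to
#' the constant model (a warning is issued and the constant model used).
#'
#' @param v observed binary vocal-sniff vector.
#' @param rate_window_W kernel FWHM in sniffs (>= 1).
#' @param n_surrogates ensemble size.
#' @param seed RNG seed.
#' @return `usv_surrogate_ensemble`, as for
#'   [constant_probability_surrogates()]; `p` is the per-sniff probability.
#' @export
variable_probability_surrogates <- function(v, rate_window_W, n_surrogates = 1000,
                                            seed = 1L) {
  if (rate_window_W < 1) abort("rate_window_W must be >= 1")
  v <- as.integer(as.logical(v))
  if (rate_window_W >= length(v)) {
    warn("rate estimation window exceeds the vector length; using the constant model")
    return(constant_probability_surrogates(v, n_surrogates, seed))
  }
  p <- local_call_probability(v, rate_window_W)
  make_surrogate_ensemble(p, n_surrogates, seed, model = "variable",
                          p_store = p, W = rate_window_W)
}

#' Gaussian-smoothed local call probability
#'
#' @param v binary vector.
#' @param W kernel FWHM in sniffs.
#' @return per-sniff probability in `[0, 1]`.
#' @export
local_call_probability <- function(v, W) {
  sigma <- W / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  kern <- kern / sum(kern)
  n <- length(v)
  num <- stats::filter(c(rep(0, half), v, rep(0, half)), kern, sides = 2L)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), kern, sides = 2L)
  p <- as.numeric(num[(half + 1L):(half + n)]) /
    as.numeric(den[(half + 1L):(half + n)])
  pmin(pmax(p, 0), 1)
}

make_surrogate_ensemble <- function(p, n_surrogates, seed, model, p_store,
                                    W = NA_real_) {
  if (n_surrogates < 1) abort("n_surrogates must be >= 1")
  set.seed(seed)
  n <- length(p)
  counts <- integer(0)
  batch <- max(1L, min(n_surrogates, floor(2e7 / n)))
  done <- 0L
  while (done < n_surrogates) {
    b <- min(batch, n_surrogates - done)
    mat <- matrix(rbinom(b * n, 1L, rep(p, each = b)), nrow = b)
    cb <- pooled_bout_counts(mat)
    if (length(cb) > length(counts)) counts <- c(counts, integer(length(cb) - length(counts)))
    if (length(cb)) counts[seq_along(cb)] <- counts[seq_along(cb)] + cb
    done <- done + b
  }
  nb <- sum(counts)
  structure(list(model = model, n_surrogates = n_surrogates, p = p_store,
                 W = W, n_bouts = nb,
                 counts = tibble::tibble(length = seq_along(counts),
                                         count = counts,
                                         prob = if (nb) counts / nb else rep(0, length(counts)))),
            class = "usv_surrogate_ensemble")
}

#' Log-likelihood ratio of observed vs. surrogate bout lengths
#'
#' `log10` of the ratio between the probability of observing a bout of a
#' given length in the real data and in the pooled surrogate ensemble; a
#' value of 1 means the length is ten times more likely in the real data.
#' Ensemble lengths never observed receive a pseudocount of 0.5 bouts so the
#' ratio stays finite.
#'
#' @param v observed binary vocal-sniff vector (or a [bout_distribution()]).
#' @param ensemble a `usv_surrogate_ensemble`.
#' @param lengths bout lengths to evaluate (1 to 5 by convention).
#' @param pseudocount count substituted for empty ensemble bins.
#' @return tibble: `length`, `p_real`, `p_surrogate`, `llr`.
#' @export
bout_log_likelihood_ratio <- function(v, ensemble, lengths = 1:5,
                                      pseudocount = 0.5) {
  real <- if (is.data.frame(v)) v else bout_distribution(extract_bouts(v))
  if (!nrow(real) || sum(real$count) == 0)
    abort("no bouts in the observed data; likelihood ratio undefined")
  n_real <- sum(real$count)
  p_real <- real$prob[match(lengths, real$length)]
  p_real[is.na(p_real)] <- 0
  surr <- ensemble$counts
  cnt <- surr$count[match(lengths, surr$length)]
  cnt[is.na(cnt)] <- 0L
  cnt_adj <- ifelse(cnt == 0L, pseudocount, as.numeric(cnt))
  p_surr <- cnt_adj / max(ensemble$n_bouts, 1)
  tibble::tibble(length = lengths, p_real = p_real, p_surrogate = p_surr,
                 llr = log10(p_real / p_surr))
}

#' Likelihood-ratio sweep over rate-estimation windows
#'
#' Runs the variable-probability surrogate analysis for a family of rate
#' estimation windows and reports the per-length log-likelihood ratios,
#' prefixed by the constant model. The window minimizing the summed |LLR|
#' estimates the timescale of the call-rate fluctuations that best explains
#' the observed bout structure.
#'
#' @param v observed binary vocal-sniff vector.
#' @param windows FWHM values in sniffs (4-256 by convention).
#' @param n_surrogates ensemble size per window.
#' @param seed master seed; per-window seeds are derived from it.
#' @param lengths bout lengths for the LLR.
#' @return tibble of class `usv_bout_llr`: `model`, `W`, `length`, `llr`.
#' @export
llr_window_sweep <- function(v, windows = c(4, 8, 12, 16, 24, 32, 48, 64, 96,
                                            128, 192, 256),
                             n_surrogates = 1000, seed = 1L, lengths = 1:5) {
  res <- list()
  ens0 <- constant_probability_surrogates(v, n_surrogates, seed_from(seed, 0))
  llr0 <- bout_log_likelihood_ratio(v, ens0, lengths)
  res[[1]] <- dplyr::mutate(llr0[, c("length", "llr")], model = "constant",
                            W = NA_real_, .before = 1L)
  for (i in seq_along(windows)) {
    ens <- variable_probability_surrogates(v, windows[i], n_surrogates,
                                           seed_from(seed, i))
    llr <- bout_log_likelihood_ratio(v, ens, lengths)
    res[[i + 1L]] <- dplyr::mutate(llr[, c("length", "llr")], model = "variable",
                                   W = windows[i], .before = 1L)
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("usv_bout_llr", class(out))
  out
}
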