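stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(sprintf("`%s` must be a single positive number", what))
  invisible(x)
}

#' Merge a set of possibly overlapping intervals
#'
#' Intervals are given as onset/offset columns; the result is the minimal set
#' of disjoint intervals covering the same time. Used when pooling emission
#' segments before computing coverage statistics.
#'
#' @param x data frame with numeric `onset` and `offset` columns (seconds).
#' @return tibble with disjoint, sorted `onset`/`offset`.
#' @keywords internal
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(tibble::tibble(onset = numeric(), offset = numeric()))
  x <- x[order(x$onset), , drop = FALSE]
  on <- x$onset; off <- x$offset
  keep_on <- on[1]; keep_off <- off[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_along(on)[-1]) {
    if (on[i] <= keep_off) {
      keep_off <- max(keep_off, off[i])
    } else {
      res_on <- c(res_on, keep_on); res_off <- c(res_off, keep_off)
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  tibble::tibble(onset = c(res_on, keep_on), offset = c(res_off, keep_off))
}

# total overlap of [a, b] with a set of disjoint sorted intervals, via the
# cumulative-coverage function evaluated at both ends
interval_coverage <- function(merged, a, b) {
  if (nrow(merged) == 0L) return(rep(0, length(a)))
  cum <- c(0, cumsum(merged$offset - merged$onset))
  cov_at <- function(t) {
    i <- findInterval(t, merged$onset)
    base <- cum[i + 1L]
    inside <- i > 0L & t < merged$offset[pmax(i, 1L)]
    base[inside] <- cum[i[inside]] + (t[inside] - merged$onset[i[inside]])
    base
  }
  cov_at(b) - cov_at(a)
}

# 32-bit polynomial rolling hash over a deparsed object; fingerprints
# configurations in run logs without a hashing dependency
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

seed_from <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset) %% 2147483647)
}
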