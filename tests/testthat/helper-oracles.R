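# Independent brute-force oracles used by the unit tests. Each is written as
# a direct transcription of the definition, sample by sample, deliberately
# ignoring the vectorized/compiled paths in the package.

# Shannon entropy by explicit summation
oracle_entropy <- function(p) {
  s <- 0
  tot <- sum(p)
  for (v in p) {
    q <- v / tot
    if (q > 0) s <- s - q * log2(q)
  }
  s
}

# run-length segmentation of a boolean below-threshold trace sampled at
# uniform frame times: merge below-runs separated by gaps <= bounding, drop
# segments with extent < min_dur. Returns data.frame(onset, offset).
oracle_segments <- function(below, times, min_dur, bounding) {
  runs <- list()
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(times[i], times[j])
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(onset = numeric(), offset = numeric()))
  segs <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- segs[[length(segs)]]
    if (r[1] - last[2] <= bounding) {
      segs[[length(segs)]] <- c(last[1], r[2])
    } else segs[[length(segs) + 1]] <- r
  }
  out <- do.call(rbind, segs)
  out <- out[out[, 2] - out[, 1] >= min_dur, , drop = FALSE]
  data.frame(onset = out[, 1], offset = out[, 2])
}

# sample-scan threshold-crossing detector with hysteresis: walks the trace,
# arming on confirmed +-hyst excursions, and interpolates the last threshold
# crossing preceding each confirmation
oracle_crossings <- function(x, sr, thr = 0, hyst = 0.05) {
  up <- numeric(0); down <- numeric(0)
  state <- 0L
  for (i in seq_along(x)) {
    s <- if (x[i] > thr + hyst) 1L else if (x[i] < thr - hyst) -1L else 0L
    if (s == 0L || s == state) next
    if (state != 0L) {
      # confirmed transition; back-scan for the last crossing of thr
      for (j in (i - 1):1) {
        if (s == 1L && x[j] <= thr && x[j + 1] > thr) {
          up <- c(up, (j - 1 + (thr - x[j]) / (x[j + 1] - x[j])) / sr)
          break
        }
        if (s == -1L && x[j] >= thr && x[j + 1] < thr) {
          down <- c(down, (j - 1 + (thr - x[j]) / (x[j + 1] - x[j])) / sr)
          break
        }
      }
    }
    state <- s
  }
  list(up = up, down = down)
}

# run lengths of ones via string scan
oracle_bouts <- function(v) {
  s <- paste(as.integer(v), collapse = "")
  parts <- strsplit(s, "0+")[[1]]
  nchar(parts[nchar(parts) > 0])
}

# smooth random trace for segmentation property tests
make_smooth_trace <- function(n, sr = 1000, seed = 1) {
  set.seed(seed)
  f <- signal::butter(2, 8 / (sr / 2), type = "low")
  x <- signal::filtfilt(f, rnorm(n + 400))
  x <- x[201:(200 + n)]
  (x - mean(x)) / sd(x)
}

# small rat config for fast tests
fast_rat_config <- function(...) {
  generator_config("rat", audio_sr = 192000, ...)
}

fast_params <- function(...) spectrogram_params(freq_hi = 96, ...)

# broadband reference with exactly flat spectral magnitude (random phase),
# the idealized calibration signal for transfer-function estimation
flat_broadband <- function(n, seed = 1) {
  set.seed(seed)
  X <- fft(rnorm(n))
  X <- X / pmax(Mod(X), 1e-12)
  Re(fft(X, inverse = TRUE)) / n
}
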