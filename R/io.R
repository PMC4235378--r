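#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer supporting IEEE float32 (default, lossless for
#' synthetic data) and PCM 16-bit.
#'
#' @param samples numeric vector; for `"pcm16"` values are clipped to
#'   `[-1, 1]` and scaled.
#' @param sr sampling rate, Hz.
#' @param path output file.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sr, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bps <- if (format == "float32") 4L else 2L
  fmt_code <- if (format == "float32") 3L else 1L
  data_bytes <- n * bps
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * bps), con, size = 4, endian = "little")
  writeBin(as.integer(bps), con, size = 2, endian = "little")
  writeBin(8L * bps, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    x <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
    writeBin(x, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()] (PCM16 or float32)
#'
#' @param path WAV file.
#' @return `list(samples, sr)`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") abort("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") abort("not a WAVE file")
  fmt_code <- NULL; sr <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1, 2, endian = "little")
      nch <- readBin(con, "integer", 1, 2, endian = "little")
      if (nch != 1L) abort("only mono WAV files are supported")
      sr <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16L))
    } else if (id == "data") {
      if (is.null(fmt_code)) abort("malformed WAV: data before fmt chunk")
      if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", size / 4L, 4, endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", size / 2L, 2, signed = TRUE,
                           endian = "little") / 32767
      } else abort("unsupported WAV encoding (need PCM16 or float32)")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) abort("no data chunk found")
  list(samples = samples, sr = sr)
}

#' Write a pressure trace as single-column CSV with a metadata sidecar
#'
#' @param samples numeric pressure trace.
#' @param sr sampling rate, Hz.
#' @param path CSV path; a `.json` sidecar with `sampling_rate_hz` is written
#'   next to it.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(samples, sr, path) {
  write.csv(data.frame(pressure = samples), path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = sr),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a pressure CSV written by [write_pressure_csv()]
#' @param path CSV path.
#' @return `list(samples, sr)`.
#' @export
read_pressure_csv <- function(path) {
  meta <- paste0(tools::file_path_sans_ext(path), ".json")
  sr <- if (file.exists(meta)) jsonlite::read_json(meta)$sampling_rate_hz else 1000
  list(samples = read.csv(path)$pressure, sr = sr)
}

#' Write ground-truth or detected events as CSV
#'
#' Long format with one row per event landmark: `subject`, `onset_s`,
#' `offset_s`, `kind` (`call`, `inh_on`, `inh_off`, `exh_off`).
#'
#' @param session a `usv_session`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(session, path) {
  rows <- purrr::imap_dfr(session$subjects, function(sub, s) {
    sn <- sub$sniffs
    dplyr::bind_rows(
      tibble::tibble(subject = s, onset_s = sub$calls$onset,
                     offset_s = sub$calls$offset, kind = "call"),
      tibble::tibble(subject = s, onset_s = sn$t_inh_on, offset_s = NA_real_,
                     kind = "inh_on"),
      tibble::tibble(subject = s, onset_s = sn$t_inh_off, offset_s = NA_real_,
                     kind = "inh_off"),
      tibble::tibble(subject = s, onset_s = sn$t_exh_off, offset_s = NA_real_,
                     kind = "exh_off"))
  })
  write.csv(format_times(rows), path, row.names = FALSE)
  invisible(path)
}

format_times <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) &
    grepl("_s$|_ms$|onset|offset", names(df))
  df[num] <- lapply(df[num], function(x) round(x, 6))
  df
}

#' Write a session to disk (audio WAVs, pressure CSVs, truth, manifest)
#'
#' @param session a `usv_session` from [simulate_session()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  audio_paths <- character(0)
  if (!is.null(session$audio)) {
    audio_paths <- purrr::imap_chr(session$audio, function(ch, i) {
      p <- file.path(dir, sprintf("audio_ch%d.wav", i))
      write_wav(ch$samples, ch$sr, p)
      p
    })
  }
  pressure_paths <- purrr::imap_chr(session$subjects, function(sub, i) {
    p <- file.path(dir, sprintf("pressure_s%d.csv", i))
    write_pressure_csv(sub$pressure$raw, sub$pressure$sr, p)
    pc <- file.path(dir, sprintf("pressure_clean_s%d.csv", i))
    write_pressure_csv(sub$pressure$clean, sub$pressure$sr, pc)
    p
  })
  truth_path <- file.path(dir, "ground_truth.csv")
  write_truth_csv(session, truth_path)
  manifest <- list(
    subjects = seq_along(session$subjects),
    species = session$config$species,
    seed = session$seed,
    duration_s = session$duration,
    audio = as.list(basename(audio_paths)),
    pressure = as.list(basename(pressure_paths)),
    audio_sr_hz = if (length(audio_paths)) session$audio[[1]]$sr else NULL,
    pressure_sr_hz = session$subjects[[1]]$pressure$sr,
    ground_truth = basename(truth_path),
    tubing_tf = list(fc_hz = session$config$tubing_tf$fc_hz,
                     delay_s = session$config$tubing_tf$delay_s)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read and validate a session manifest
#'
#' @param path manifest JSON path.
#' @return the manifest as a list, with absolute paths; errors if referenced
#'   files are missing or sampling rates are undeclared.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(normalizePath(path))
  for (key in c("audio", "pressure")) {
    if (is.null(m[[key]])) next
    m[[key]] <- file.path(dir, unlist(m[[key]]))
    missing <- !file.exists(m[[key]])
    if (any(missing))
      abort(sprintf("manifest references missing %s file(s): %s", key,
                    paste(basename(m[[key]][missing]), collapse = ", ")))
  }
  if (!is.null(m$ground_truth)) m$ground_truth <- file.path(dir, m$ground_truth)
  if (length(m$audio) && is.null(m$audio_sr_hz))
    abort("manifest must declare audio_sr_hz")
  if (is.null(m$pressure_sr_hz)) abort("manifest must declare pressure_sr_hz")
  m
}
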