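# Audio input/output and quality screening.
#
# Recordings are plain-vanilla PCM WAV files (the format written by digital
# stethoscopes after export); no R audio package is required. Only 16-bit
# mono (or stereo with an explicit mixdown) linear PCM is supported, which
# covers the acquisition format used for phonoenterography (44.1 kHz, 16-bit).

#' Construct a phonoenterogram recording object
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @param subject_id Opaque subject identifier.
#' @param quadrant Abdominal sensor site: `"LUQ"`, `"RLQ"` or `"other"`.
#' @param state Physiological state: `"fasting"`, `"postprandial"` or
#'   `"unknown"`.
#' @return An object of class `"peg_recording"` with fields `samples`,
#'   `sample_rate`, `duration_s`, `subject_id` and `session`.
#' @export
peg_recording <- function(samples, sample_rate, subject_id = "unknown",
                          quadrant = c("other", "LUQ", "RLQ"),
                          state = c("unknown", "fasting", "postprandial")) {
  quadrant <- match.arg(quadrant)
  state <- match.arg(state)
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sample_rate), sample_rate > 0)
  if (max(abs(samples)) > 1 + 1e-9)
    stop("samples must lie in [-1, 1]; normalize or rescale first")
  structure(list(
    samples = as.numeric(samples),
    sample_rate = as.integer(round(sample_rate)),
    duration_s = length(samples) / sample_rate,
    subject_id = subject_id,
    session = list(quadrant = quadrant, state = state)
  ), class = "peg_recording")
}

#' @export
print.peg_recording <- function(x, ...) {
  cat(sprintf("<peg_recording> %s | %.3f s @ %d Hz | %s/%s\n",
              x$subject_id, x$duration_s, x$sample_rate,
              x$session$quadrant, x$session$state))
  invisible(x)
}

#' Read a PCM WAV file as a recording
#'
#' Reads 16-bit linear PCM WAV. Samples are scaled to `[-1, 1]` by the
#' 16-bit full scale (32768). Multichannel files are rejected unless
#' `mixdown = TRUE`, in which case channels are averaged.
#'
#' @param path Path to a `.wav` file.
#' @param mixdown Average channels of a multichannel file to mono.
#' @inheritParams peg_recording
#' @return A [peg_recording()].
#' @export
read_wav <- function(path, mixdown = FALSE, subject_id = "unknown",
                     quadrant = "other", state = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$audio_format != 1L || fmt$bits != 16L)
    stop("unsupported WAV encoding (need 16-bit linear PCM): ", path)
  if (fmt$n_channels > 1L && !mixdown)
    stop("multichannel WAV and mixdown = FALSE: ", path)

  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2, endian = "little", signed = TRUE)
  x <- ints / 32768
  if (fmt$n_channels > 1L) {
    n <- length(x) %/% fmt$n_channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$n_channels)],
                         ncol = fmt$n_channels, byrow = TRUE))
  }
  peg_recording(x, fmt$sample_rate, subject_id = subject_id,
                quadrant = quadrant, state = state)
}

#' Write a recording to a 16-bit PCM WAV file
#'
#' @param rec A [peg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "peg_recording"))
  ints <- as.integer(pmax(pmin(round(rec$samples * 32768), 32767), -32768))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Peak-normalize a recording's amplitude
#'
#' Scales samples so the maximum absolute amplitude is exactly 1. An all-zero
#' recording is returned unchanged with a warning.
#'
#' @param rec A [peg_recording()].
#' @return The normalized recording.
#' @export
normalize_amplitude <- function(rec) {
  stopifnot(inherits(rec, "peg_recording"))
  peak <- max(abs(rec$samples))
  if (peak == 0) {
    warning("all-zero recording; returning unchanged")
    return(rec)
  }
  rec$samples <- rec$samples / peak
  rec
}

#' Quality pre-screen for clipping and ambient-noise level
#'
#' A sample is counted as clipped when its magnitude reaches 16-bit full
#' scale (`|x| >= 1 - 2^-15`). The recording passes when the clipping
#' fraction does not exceed `clip_threshold` and the RMS level lies inside
#' `rms_bounds` (a crude operationalization of "excessive ambient noise";
#' the bounds are configurable, not claimed canonical).
#'
#' @param rec A normalized [peg_recording()].
#' @param clip_threshold Maximum tolerated clipping fraction.
#' @param rms_bounds Length-2 numeric, inclusive RMS bounds.
#' @return A list of class `"peg_qc"`: `clipping_fraction`, `rms_level`,
#'   `passed`.
#' @export
prescreen <- function(rec, clip_threshold = 0.001, rms_bounds = c(1e-4, 0.9)) {
  stopifnot(inherits(rec, "peg_recording"), length(rms_bounds) == 2)
  clip <- mean(abs(rec$samples) >= 1 - 2^-15)
  rms <- sqrt(mean(rec$samples^2))
  structure(list(
    clipping_fraction = clip,
    rms_level = rms,
    passed = clip <= clip_threshold && rms >= rms_bounds[1] && rms <= rms_bounds[2]
  ), class = "peg_qc")
}

#' Read and write event annotation tables
#'
#' Annotation tables have columns `onset_s`, `offset_s`, `label` (label may
#' be empty). CSV is the primary format; a `.json` path reads/writes the JSON
#' mirror. Times are written with 6-decimal precision; rows are kept sorted
#' by onset.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A `data.frame` with columns `onset_s`, `offset_s`, `label`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(label = "character"))
  }
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param annotations Annotation `data.frame` to write.
#' @export
write_annotations <- function(annotations, path) {
  df <- validate_annotations(annotations)
  df$onset_s <- round(df$onset_s, 6)
  df$offset_s <- round(df$offset_s, 6)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

validate_annotations <- function(df) {
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(df)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$label <- as.character(df$label)
  df$label[is.na(df$label)] <- ""
  if (nrow(df) > 0) {
    if (any(df$onset_s >= df$offset_s)) stop("annotation rows must have onset_s < offset_s")
    df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
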