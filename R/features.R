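# 279-dimensional acoustic encoding of 200 ms event windows.
#
# Layout (fixed, see feature_schema()):
#   260 = 20 MFCCs x 13 frames, frame-major (all 20 coefficients of frame 1,
#         then frame 2, ...)
#    13 = time-averaged regression deltas of MFCC coefficients 1..13
#     6 = spectral centroid, bandwidth, flatness, roll-off, RMS, entropy
#
# MFCCs use a Hann window, a mel filterbank spanning 0..Nyquist, log filter
# energies and an orthonormal DCT-II. No pre-emphasis or liftering is
# applied (these are configuration choices, not claims about any particular
# reference implementation).

LOG_FLOOR <- 1e-12

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mels filters over FFT bins 0..n_fft/2.
mel_filterbank <- function(sample_rate, n_fft, n_mels = 26,
                           fmin = 0, fmax = sample_rate / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (0:(n_fft %/% 2)) * sample_rate / n_fft
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1)
  m <- 0:(n_in - 1)
  mat <- sqrt(2 / n_in) * cos(pi * outer(k, m + 0.5) / n_in)
  mat[1, ] <- sqrt(1 / n_in)
  mat
}

#' Slice a 200 ms event segment into a fixed number of frames
#'
#' The hop is derived from the segment and frame lengths so that exactly
#' `n_frames` frames cover the segment: the first frame starts at the
#' segment start and the last ends at the segment end (hop
#' `(len - frame) / (n_frames - 1)`, rounded to whole samples).
#'
#' @param segment Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param frame_s Frame length in seconds (default 25 ms).
#' @param n_frames Number of frames (default 13).
#' @return A matrix with `frame_length` rows and `n_frames` columns.
#' @export
frame_segment <- function(segment, sample_rate, frame_s = 0.025, n_frames = 13) {
  W <- as.integer(floor(frame_s * sample_rate + 0.5))  # half-up: 1103 @ 44.1 kHz
  n <- length(segment)
  if (n < W) stop("segment shorter than one frame")
  if (n_frames == 1L) return(matrix(segment[seq_len(W)], ncol = 1))
  starts <- as.integer(round(seq(0, n - W, length.out = n_frames)))
  vapply(starts, function(s) segment[(s + 1):(s + W)], numeric(W))
}

#' MFCC block of an event segment: 20 coefficients x 13 frames
#'
#' @param frames Frame matrix from [frame_segment()].
#' @param sample_rate Sampling rate in Hz.
#' @param n_mfcc Number of cepstral coefficients per frame (default 20).
#' @param n_mels Number of mel filters (default 26).
#' @return A `n_mfcc` x `n_frames` matrix of MFCCs.
#' @export
mfcc_block <- function(frames, sample_rate, n_mfcc = 20, n_mels = 26) {
  W <- nrow(frames)
  n_fft <- 2^ceiling(log2(W))
  win <- hann_window(W)
  fb <- mel_filterbank(sample_rate, n_fft, n_mels)
  dct <- dct_matrix(n_mfcc, n_mels)
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(W), ] <- frames * win
  spec <- stats::mvfft(padded)[seq_len(n_fft %/% 2 + 1), , drop = FALSE]
  power <- Mod(spec)^2
  logmel <- log(fb %*% power + LOG_FLOOR)
  dct %*% logmel
}

#' Time-averaged regression deltas of the first 13 MFCCs
#'
#' First-order regression deltas (half-window `half_window`) are computed
#' across frames on the valid interior frames only (no edge padding) and
#' averaged over time, yielding one delta per coefficient. On a coefficient
#' ramp with slope `s` per frame every delta equals `s` exactly.
#'
#' @param mfcc MFCC matrix (coefficients x frames) from [mfcc_block()].
#' @param n_delta Number of coefficients to summarize (default 13).
#' @param half_window Regression half-window in frames (default 2).
#' @return Numeric vector of `n_delta` delta summaries.
#' @export
delta_block <- function(mfcc, n_delta = 13, half_window = 2) {
  T_ <- ncol(mfcc)
  if (T_ < 3) stop("need at least 3 frames for deltas")
  hw <- min(half_window, (T_ - 1) %/% 2)
  C <- mfcc[seq_len(min(n_delta, nrow(mfcc))), , drop = FALSE]
  denom <- 2 * sum((1:hw)^2)
  valid <- (hw + 1):(T_ - hw)
  d <- matrix(0, nrow(C), length(valid))
  for (k in 1:hw) {
    d <- d + k * (C[, valid + k, drop = FALSE] - C[, valid - k, drop = FALSE])
  }
  rowMeans(d / denom)
}

#' Six scalar spectral descriptors of an event segment
#'
#' Computed on the Hann-windowed magnitude spectrum of the whole segment:
#' power-weighted centroid (Hz), power-weighted bandwidth about the centroid
#' (Hz), spectral flatness (geometric/arithmetic mean of the power
#' spectrum), roll-off frequency at cumulative power `rolloff` (Hz), RMS of
#' the raw time samples, and Shannon entropy of the normalized power
#' spectrum divided by `log(n_bins)`. An all-zero segment returns all zeros
#' with attribute `"silent" = TRUE`.
#'
#' @param segment Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param rolloff Roll-off percentile (default 0.85).
#' @return Named numeric vector: `centroid_hz`, `bandwidth_hz`, `flatness`,
#'   `rolloff_hz`, `rms`, `spectral_entropy`.
#' @export
spectral_descriptors <- function(segment, sample_rate, rolloff = 0.85) {
  nm <- c("centroid_hz", "bandwidth_hz", "flatness", "rolloff_hz", "rms",
          "spectral_entropy")
  if (all(segment == 0)) {
    out <- stats::setNames(numeric(6), nm)
    attr(out, "silent") <- TRUE
    return(out)
  }
  n <- length(segment)
  win <- hann_window(n)
  spec <- stats::fft(segment * win)
  nb <- n %/% 2 + 1
  p <- Mod(spec[seq_len(nb)])^2
  freqs <- (seq_len(nb) - 1) * sample_rate / n
  ptot <- sum(p)
  centroid <- sum(freqs * p) / ptot
  bandwidth <- sqrt(sum(p * (freqs - centroid)^2) / ptot)
  flatness <- exp(mean(log(p + LOG_FLOOR))) / (mean(p) + LOG_FLOOR)
  rolloff_hz <- freqs[which(cumsum(p) >= rolloff * ptot)[1]]
  q <- p / ptot
  ent <- -sum(ifelse(q > 0, q * log(q), 0)) / log(nb)
  stats::setNames(c(centroid, bandwidth, flatness, rolloff_hz,
                    sqrt(mean(segment^2)), ent), nm)
}

#' Names of the 279 feature columns, in frozen order
#'
#' @return Character vector of length 279.
#' @export
feature_schema <- function() {
  mf <- as.vector(vapply(1:13, function(f) sprintf("mfcc%02d_f%02d", 1:20, f),
                         character(20)))
  c(mf, sprintf("dmfcc%02d", 1:13),
    c("centroid_hz", "bandwidth_hz", "flatness", "rolloff_hz", "rms",
      "spectral_entropy"))
}

#' Encode detected events as a 279-column feature matrix
#'
#' Each event contributes one row computed from its fixed 200 ms window
#' centered on the peak. The result is unstandardized; see
#' [zscore_features()].
#'
#' @param rec A [peg_recording()].
#' @param events Event `data.frame` with `peak_time_s`.
#' @param window_s Feature window length (default 0.2 s).
#' @param frame_s,n_frames,n_mfcc,n_mels,rolloff Feature parameters.
#' @return A `peg_features` object: numeric matrix (events x 279) with
#'   column names from [feature_schema()] and attribute
#'   `standardized = FALSE`.
#' @export
featurize_events <- function(rec, events, window_s = 0.2, frame_s = 0.025,
                             n_frames = 13, n_mfcc = 20, n_mels = 26,
                             rolloff = 0.85) {
  stopifnot(inherits(rec, "peg_recording"))
  sr <- rec$sample_rate
  half <- as.integer(round(window_s * sr / 2))
  n_ev <- nrow(events)
  ncol_total <- n_mfcc * n_frames + 13 + 6
  out <- matrix(0, n_ev, ncol_total)
  if (n_ev > 0) {
    for (i in seq_len(n_ev)) {
      c_idx <- as.integer(round(events$peak_time_s[i] * sr))
      lo <- c_idx - half + 1L; hi <- c_idx + half
      if (lo < 1L || hi > length(rec$samples))
        stop("event window out of recording bounds at ",
             events$peak_time_s[i], " s")
      seg <- rec$samples[lo:hi]
      frames <- frame_segment(seg, sr, frame_s, n_frames)
      mf <- mfcc_block(frames, sr, n_mfcc, n_mels)
      out[i, ] <- c(as.vector(mf), delta_block(mf),
                    spectral_descriptors(seg, sr, rolloff))
    }
  }
  colnames(out) <- feature_schema()
  structure(out, class = c("peg_features", "matrix", "array"),
            standardized = FALSE)
}

#' Combine feature matrices from several recordings
#'
#' @param ... `peg_features` matrices (or a single list of them).
#' @return One pooled `peg_features` matrix.
#' @export
bind_features <- function(...) {
  mats <- list(...)
  if (length(mats) == 1 && is.list(mats[[1]]) && !is.matrix(mats[[1]]))
    mats <- mats[[1]]
  out <- do.call(rbind, lapply(mats, unclass))
  structure(out, class = c("peg_features", "matrix", "array"),
            standardized = FALSE)
}

#' Z-score standardize a feature matrix
#'
#' Columns are centered and scaled over all pooled events. Constant columns
#' are set to 0 and flagged. When `params` (from a previous call) is
#' supplied, its means/SDs are reused, which makes re-application with
#' stored parameters idempotent.
#'
#' @param fm A `peg_features` matrix.
#' @param params Optional list with `center` and `scale` from a previous
#'   standardization.
#' @param sd_type `"population"` (denominator N, default) or `"sample"`.
#' @return Standardized `peg_features` matrix with attributes `center`,
#'   `scale`, `constant_columns`, `standardized = TRUE`.
#' @export
zscore_features <- function(fm, params = NULL, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- unclass(fm)
  if (nrow(x) < 2 && is.null(params)) stop("need at least 2 rows to standardize")
  if (is.null(params)) {
    ctr <- colMeans(x)
    scl <- if (sd_type == "population") {
      sqrt(colMeans(sweep(x, 2, ctr)^2))
    } else {
      apply(x, 2, stats::sd)
    }
  } else {
    ctr <- params$center; scl <- params$scale
  }
  const <- scl < 1e-12
  scl_safe <- ifelse(const, 1, scl)
  z <- sweep(sweep(x, 2, ctr), 2, scl_safe, "/")
  if (is.null(params)) {
    # near-constant columns amplify float residue of the centering; a second
    # centering pass (folded into the stored center) restores exact zero mean
    resid <- colMeans(z)
    z <- sweep(z, 2, resid)
    ctr <- ctr + resid * scl_safe
  }
  z[, const] <- 0
  structure(z, class = c("peg_features", "matrix", "array"),
            standardized = TRUE, center = ctr, scale = scl,
            constant_columns = which(const))
}
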