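# Prominent bowel-sound event detection.
#
# Events are local maxima of a short-time energy envelope exceeding a
# dynamic threshold (mean + 2 SD of the envelope); each retained peak is
# assigned a fixed 200 ms feature window (100 ms either side of the peak)
# and, separately, hysteresis-based onset/offset boundaries that may extend
# well beyond the window for sustained sounds.

#' Short-time energy envelope
#'
#' Mean squared amplitude per frame, framed with `window_s` length and
#' `hop_s` step. Frame times are frame centers in seconds.
#'
#' @param rec A [peg_recording()].
#' @param window_s Frame length in seconds (default 25 ms).
#' @param hop_s Frame step in seconds (default 5 ms).
#' @return An object of class `"peg_envelope"` with fields `frame_times_s`,
#'   `values`, `window_s`, `hop_s`, `duration_s`.
#' @export
short_time_energy <- function(rec, window_s = 0.025, hop_s = 0.005) {
  stopifnot(inherits(rec, "peg_recording"), window_s > hop_s, hop_s > 0)
  sr <- rec$sample_rate
  W <- max(1L, as.integer(round(window_s * sr)))
  H <- max(1L, as.integer(round(hop_s * sr)))
  n <- length(rec$samples)
  if (n < W) stop("recording shorter than one analysis window")
  n_frames <- 1L + (n - W) %/% H
  cs <- c(0, cumsum(rec$samples^2))
  starts <- (seq_len(n_frames) - 1L) * H
  values <- (cs[starts + W + 1L] - cs[starts + 1L]) / W
  structure(list(
    frame_times_s = (starts + W / 2) / sr,
    values = values,
    window_s = W / sr,
    hop_s = H / sr,
    duration_s = rec$duration_s
  ), class = "peg_envelope")
}

#' Dynamic detection threshold: mean + `n_sd` standard deviations
#'
#' The SD uses the population convention (denominator N); this is a
#' documented, configurable choice.
#'
#' @param env A [short_time_energy()] envelope.
#' @param n_sd Number of SDs above the mean (default 2).
#' @param sd_type `"population"` (denominator N) or `"sample"` (N - 1).
#' @return A single energy value.
#' @export
dynamic_threshold <- function(env, n_sd = 2, sd_type = c("population", "sample")) {
  stopifnot(inherits(env, "peg_envelope"))
  sd_type <- match.arg(sd_type)
  v <- env$values
  if (length(v) < 2) stop("need at least 2 envelope frames")
  s <- if (sd_type == "population") sd_pop(v) else stats::sd(v)
  m <- mean(v)
  # tiny relative floor so float ripple on a flat envelope never counts as
  # super-threshold structure
  max(m + n_sd * s, m * (1 + 1e-12))
}

#' Detect prominent events as super-threshold envelope peaks
#'
#' A frame is a peak when its value exceeds `threshold` and is not smaller
#' than either immediate neighbor; plateau ties are broken leftward. Each
#' peak yields one event carrying the fixed 200 ms feature window
#' (`peak - window_s/2`, `peak + window_s/2`); events whose window would
#' cross a file edge are dropped.
#'
#' @param env A [short_time_energy()] envelope.
#' @param threshold Energy threshold, typically from [dynamic_threshold()].
#' @param window_s Feature window length in seconds (default 0.2).
#' @return A `data.frame` with columns `peak_time_s`, `onset_s`, `offset_s`,
#'   `peak_energy` (onset/offset initialized to the window bounds).
#' @export
detect_events <- function(env, threshold, window_s = 0.2) {
  stopifnot(inherits(env, "peg_envelope"))
  v <- env$values
  n <- length(v)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  is_peak <- v > threshold & v > left & v >= right
  idx <- which(is_peak)
  t_peak <- env$frame_times_s[idx]
  half <- window_s / 2
  keep <- t_peak - half >= 0 & t_peak + half <= env$duration_s
  idx <- idx[keep]; t_peak <- t_peak[keep]
  out <- data.frame(
    peak_time_s = t_peak,
    onset_s = t_peak - half,
    offset_s = t_peak + half,
    peak_energy = v[idx]
  )
  attr(out, "window_s") <- window_s
  out
}

#' Resolve closely spaced events
#'
#' Peaks closer than `min_separation_s` form conflict chains (transitive
#' closeness). In `"discard"` mode (the strict reading) every member of a
#' chain is removed; in `"strongest"` mode the highest-energy member of each
#' chain is kept. Either way, surviving events are pairwise at least
#' `min_separation_s` apart.
#'
#' @param events Event `data.frame` sorted by `peak_time_s`.
#' @param min_separation_s Minimum peak separation in seconds (default 0.1).
#' @param mode `"discard"` or `"strongest"`.
#' @return The filtered event `data.frame`.
#' @export
proximity_filter <- function(events, min_separation_s = 0.1,
                             mode = c("discard", "strongest")) {
  mode <- match.arg(mode)
  n <- nrow(events)
  if (n <= 1) return(events)
  if (is.unsorted(events$peak_time_s)) stop("events must be sorted by peak_time_s")
  gap <- diff(events$peak_time_s)
  chain_id <- cumsum(c(1, as.integer(gap >= min_separation_s)))
  keep <- logical(n)
  for (id in unique(chain_id)) {
    members <- which(chain_id == id)
    if (length(members) == 1L) {
      keep[members] <- TRUE
    } else if (mode == "strongest") {
      keep[members[which.max(events$peak_energy[members])]] <- TRUE
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_s") <- attr(events, "window_s")
  out
}

#' Hysteresis onset/offset estimation around a detected peak
#'
#' Event boundaries are found by descending from the peak until the envelope
#' falls below `onset_fraction * threshold`: the onset is the last frame
#' before the peak below that level and the offset the first such frame
#' after. Boundaries are never narrower than the fixed feature window
#' (`min_window_s`), so short impulses report the window itself while
#' sustained sounds report their full extent.
#'
#' @param env A [short_time_energy()] envelope.
#' @param peak_time_s Peak time of a detected event, seconds.
#' @param threshold The detection threshold used for this envelope.
#' @param onset_fraction Fraction of `threshold` defining the boundary level.
#' @param min_window_s Minimum event extent, seconds (default 0.2).
#' @return Numeric vector `c(onset_s, offset_s)`.
#' @export
estimate_boundaries <- function(env, peak_time_s, threshold,
                                onset_fraction = 0.5, min_window_s = 0.2) {
  stopifnot(inherits(env, "peg_envelope"))
  i <- which.min(abs(env$frame_times_s - peak_time_s))
  if (env$values[i] <= threshold) stop("peak is not above threshold")
  level <- onset_fraction * threshold
  below <- env$values < level
  prev <- which(below & seq_along(below) < i)
  nxt <- which(below & seq_along(below) > i)
  onset <- if (length(prev)) env$frame_times_s[max(prev)] else env$frame_times_s[1]
  offset <- if (length(nxt)) env$frame_times_s[min(nxt)] else env$frame_times_s[length(below)]
  half <- min_window_s / 2
  onset <- max(min(onset, peak_time_s - half), 0)
  offset <- min(max(offset, peak_time_s + half), env$duration_s)
  c(onset_s = onset, offset_s = offset)
}

#' Score detections against a reference annotation table
#'
#' Detected peaks are matched one-to-one to reference onsets greedily in
#' order of increasing absolute time difference; only pairs within
#' `tolerance_s` match. Precision is matched/detected, recall is
#' matched/reference and F1 their harmonic mean (0 when both are 0).
#'
#' @param detected Event `data.frame` with `peak_time_s`, or a numeric
#'   vector of peak times.
#' @param reference Annotation `data.frame` with `onset_s`.
#' @param tolerance_s Matching tolerance, seconds (default 0.1).
#' @return A list of class `"peg_match"`: `n_detected`, `n_reference`,
#'   `n_matched`, `precision`, `recall`, `f1`, `tolerance_s`.
#' @export
match_events <- function(detected, reference, tolerance_s = 0.1) {
  t_det <- if (is.data.frame(detected)) detected$peak_time_s else as.numeric(detected)
  t_ref <- if (is.data.frame(reference)) reference$onset_s else as.numeric(reference)
  nd <- length(t_det); nr <- length(t_ref)
  pairs <- data.frame(detected = integer(0), reference = integer(0))
  if (nd > 0 && nr > 0) {
    dmat <- abs(outer(t_det, t_ref, "-"))
    cand <- which(dmat <= tolerance_s, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_d <- logical(nd); used_r <- logical(nr)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!used_d[i] && !used_r[j]) {
          used_d[i] <- TRUE; used_r[j] <- TRUE
          pairs <- rbind(pairs, data.frame(detected = i, reference = j))
        }
      }
    }
  }
  n_matched <- nrow(pairs)
  precision <- if (nd > 0) n_matched / nd else 0
  recall <- if (nr > 0) n_matched / nr else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(n_detected = nd, n_reference = nr, n_matched = n_matched,
                 precision = precision, recall = recall, f1 = f1,
                 tolerance_s = tolerance_s, pairs = pairs),
            class = "peg_match")
}

#' @export
print.peg_match <- function(x, ...) {
  cat(sprintf(
    "<peg_match> matched %d/%d ref (recall %.3f), %d det (precision %.3f), F1 %.4f @ +/-%.0f ms\n",
    x$n_matched, x$n_reference, x$recall, x$n_detected, x$precision, x$f1,
    1000 * x$tolerance_s))
  invisible(x)
}

#' Full event detection on one recording
#'
#' Convenience wrapper chaining [short_time_energy()], [dynamic_threshold()],
#' [detect_events()], [proximity_filter()] and [estimate_boundaries()].
#'
#' @inheritParams short_time_energy
#' @inheritParams dynamic_threshold
#' @inheritParams proximity_filter
#' @inheritParams estimate_boundaries
#' @param feature_window_s Fixed per-event feature window, seconds.
#' @return Event `data.frame` (`peak_time_s`, `onset_s`, `offset_s`,
#'   `peak_energy`) with the threshold stored as attribute `"threshold"`.
#' @export
detect_recording <- function(rec, window_s = 0.025, hop_s = 0.005, n_sd = 2,
                             feature_window_s = 0.2, min_separation_s = 0.1,
                             mode = "strongest", onset_fraction = 0.5) {
  env <- short_time_energy(rec, window_s, hop_s)
  thr <- dynamic_threshold(env, n_sd)
  ev <- detect_events(env, thr, feature_window_s)
  ev <- proximity_filter(ev, min_separation_s, mode)
  if (nrow(ev) > 0) {
    b <- t(vapply(ev$peak_time_s, function(p)
      estimate_boundaries(env, p, thr, onset_fraction, feature_window_s),
      numeric(2)))
    ev$onset_s <- b[, 1]
    ev$offset_s <- b[, 2]
  }
  attr(ev, "threshold") <- thr
  attr(ev, "window_s") <- feature_window_s
  ev
}
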