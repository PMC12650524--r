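# First-order Markov temporal modeling of labeled event sequences.
#
# Events are (t_start, t_end, state) triples ordered by start time within
# each file. Transitions are counted over consecutive pairs within files
# and pooled across files; probabilities come from row normalization with a
# tiny epsilon in the denominator so states with no outgoing transitions
# yield all-zero rows. Dwell times use the sample (N-1) SD convention.

#' Build per-file time-ordered event sequences
#'
#' @param events A `data.frame` with columns `file`, `onset_s`, `offset_s`
#'   and `state` (integer labels `0..K-1`).
#' @param K Number of states (default: `max(state) + 1`).
#' @return A list of class `"peg_sequences"`: one `data.frame` per file,
#'   each sorted by onset (ties by offset, then input order), with
#'   attribute `K`.
#' @export
build_sequences <- function(events, K = NULL) {
  need <- c("file", "onset_s", "offset_s", "state")
  if (!all(need %in% names(events)))
    stop("events needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(events$state))) stop("every event must be labeled")
  if (any(events$offset_s < events$onset_s)) stop("offset_s < onset_s")
  if (is.null(K)) K <- if (nrow(events)) max(events$state) + 1L else 0L
  if (nrow(events) && any(events$state < 0 | events$state >= K))
    stop("state out of range 0..K-1")
  seqs <- lapply(split(seq_len(nrow(events)), events$file), function(idx) {
    df <- events[idx, , drop = FALSE]
    df <- df[order(df$onset_s, df$offset_s, seq_len(nrow(df))), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  structure(seqs, class = "peg_sequences", K = as.integer(K))
}

#' Pooled transition count matrix
#'
#' Counts consecutive within-file state pairs `(z_n, z_{n+1})`, pooled
#' across files; no pair crosses a file boundary.
#'
#' @param sequences A [build_sequences()] result (or a plain list of
#'   data.frames with a `state` column).
#' @param K Number of states.
#' @return Integer `K x K` matrix `N` with `N[i, j]` = transitions from
#'   state `i-1` to `j-1`.
#' @export
transition_counts <- function(sequences, K = attr(sequences, "K")) {
  stopifnot(!is.null(K))
  N <- matrix(0L, K, K)
  for (df in sequences) {
    z <- df$state
    if (any(z >= K | z < 0)) stop("state out of range 0..K-1")
    if (length(z) >= 2) {
      from <- z[-length(z)] + 1L
      to <- z[-1] + 1L
      for (t in seq_along(from)) N[from[t], to[t]] <- N[from[t], to[t]] + 1L
    }
  }
  N
}

#' Row-normalized transition probabilities
#'
#' `P[i, j] = N[i, j] / (sum_j N[i, j] + eps)`. The epsilon keeps rows with
#' no outgoing transitions at exactly zero instead of dividing by zero.
#'
#' @param N Nonnegative count matrix.
#' @param eps Denominator constant (default `1e-9`).
#' @return Matrix of probabilities; rows with data sum to 1 within
#'   `K * eps`, empty rows sum to 0.
#' @export
transition_probabilities <- function(N, eps = 1e-9) {
  stopifnot(all(N >= 0))
  sweep(N, 1, rowSums(N) + eps, "/")
}

#' Per-state dwell-time statistics
#'
#' Dwell of an event is `t_end - t_start`. Means use all events of the
#' state; SDs use the sample (N-1) convention and are `NA` for states with
#' fewer than two events.
#'
#' @inheritParams transition_counts
#' @return A `data.frame` with columns `state`, `n_events`, `mean_dwell_s`,
#'   `sd_dwell_s`.
#' @export
dwell_stats <- function(sequences, K = attr(sequences, "K")) {
  all_df <- do.call(rbind, lapply(sequences, function(df)
    df[c("state", "onset_s", "offset_s")]))
  if (is.null(all_df)) all_df <- data.frame(state = integer(),
                                            onset_s = numeric(),
                                            offset_s = numeric())
  d <- all_df$offset_s - all_df$onset_s
  if (any(d < 0)) stop("negative dwell time (offset < onset)")
  out <- data.frame(state = 0:(K - 1), n_events = 0L,
                    mean_dwell_s = NA_real_, sd_dwell_s = NA_real_)
  for (k in 0:(K - 1)) {
    dk <- d[all_df$state == k]
    out$n_events[k + 1] <- length(dk)
    if (length(dk) >= 1) out$mean_dwell_s[k + 1] <- mean(dk)
    if (length(dk) >= 2) out$sd_dwell_s[k + 1] <- stats::sd(dk)
  }
  out
}

#' Global inter-event gap statistics
#'
#' The gap is `t_{n+1}^start - t_n^end` for consecutive events of the same
#' file; gaps never cross file boundaries. Overlapping consecutive events
#' yield negative gaps, which are retained with a warning by default (they
#' are rare once close events are filtered upstream); `drop_negative = TRUE`
#' removes them.
#'
#' @inheritParams transition_counts
#' @param drop_negative Drop negative gaps instead of keeping them.
#' @return A list of class `"peg_gaps"`: `mean_gap_s`, `sd_gap_s` (sample
#'   SD), `n_gaps`, `n_negative`.
#' @export
gap_stats <- function(sequences, drop_negative = FALSE) {
  gaps <- unlist(lapply(sequences, function(df) {
    n <- nrow(df)
    if (n < 2) return(numeric(0))
    df$onset_s[-1] - df$offset_s[-n]
  }), use.names = FALSE)
  n_neg <- sum(gaps < 0)
  if (n_neg > 0) {
    if (drop_negative) gaps <- gaps[gaps >= 0]
    else warning(n_neg, " negative gap(s) from overlapping events retained")
  }
  structure(list(
    mean_gap_s = if (length(gaps)) mean(gaps) else NA_real_,
    sd_gap_s = if (length(gaps) >= 2) stats::sd(gaps) else NA_real_,
    n_gaps = length(gaps), n_negative = n_neg
  ), class = "peg_gaps")
}

#' Fit the full first-order Markov temporal model
#'
#' @inheritParams transition_counts
#' @param eps Epsilon for row normalization.
#' @return A list of class `"peg_transition_model"`: `counts`,
#'   `probabilities`, `dwell`, `gaps`, `K`, `n_sequences`, `n_transitions`.
#' @export
fit_transition_model <- function(sequences, K = attr(sequences, "K"),
                                 eps = 1e-9) {
  N <- transition_counts(sequences, K)
  structure(list(
    counts = N,
    probabilities = transition_probabilities(N, eps),
    dwell = dwell_stats(sequences, K),
    gaps = gap_stats(sequences),
    K = K,
    n_sequences = length(sequences),
    n_transitions = sum(N)
  ), class = "peg_transition_model")
}

#' Simulate a labeled event sequence from a Markov model
#'
#' Draws a state chain from the row-stochastic matrix `P`, a dwell duration
#' per event from the state's law and a gap before each subsequent event
#' from the gap law; timestamps accumulate.
#'
#' @param P Row-stochastic `K x K` transition matrix (rows reachable from
#'   `init_state` must sum to 1).
#' @param dwell_laws List of `K` [tnorm_law()] objects (state dwell laws).
#' @param gap_law A [tnorm_law()] for inter-event gaps.
#' @param n_events Number of events to simulate.
#' @param init_state Starting state (default drawn uniformly).
#' @param file_id File identifier for the output.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `file`, `onset_s`, `offset_s`,
#'   `state`.
#' @export
simulate_markov <- function(P, dwell_laws, gap_law, n_events,
                            init_state = NULL, file_id = "sim", seed = NULL) {
  K <- nrow(P)
  stopifnot(ncol(P) == K, length(dwell_laws) == K)
  with_seed(seed, {
    z <- integer(n_events)
    z[1] <- if (is.null(init_state)) sample.int(K, 1) - 1L else init_state
    for (n in seq_len(n_events - 1)) {
      row <- P[z[n] + 1L, ]
      if (abs(sum(row) - 1) > 1e-6)
        stop("non-stochastic row ", z[n], " reached during simulation")
      z[n + 1] <- sample.int(K, 1, prob = row) - 1L
    }
    dw <- vapply(z, function(s) rtnorm(1, dwell_laws[[s + 1L]]), numeric(1))
    gp <- c(0, rtnorm(n_events - 1, gap_law))
    onset <- cumsum(gp) + c(0, cumsum(dw))[seq_len(n_events)]
    data.frame(file = file_id, onset_s = onset, offset_s = onset + dw,
               state = z)
  })
}
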