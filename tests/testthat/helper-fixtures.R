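# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately use naive loops so they stay independent of the
# vectorized implementations they check.

# A tone recording: `bursts` list of (time_s, dur_s, freq, amp[, shape])
# placed in near-silence (tiny dither so normalization is well defined).
# shape "sine2" is a symmetric sin^2 bump; "flat" is a sustained tone with
# 10 ms raised-cosine edges.
make_tone_recording <- function(duration_s = 10, sample_rate = 8000,
                                bursts = list(), noise_sd = 1e-4,
                                seed = 1) {
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  x <- rnorm(n, 0, noise_sd)
  t <- (seq_len(n) - 1) / sample_rate
  for (b in bursts) {
    idx <- which(t >= b$time_s & t < b$time_s + b$dur_s)
    tt <- t[idx] - b$time_s
    env <- if (identical(b$shape, "flat")) {
      e <- rep(1, length(tt))
      r <- 0.01
      e[tt < r] <- sin(pi * tt[tt < r] / (2 * r))^2
      e[tt > b$dur_s - r] <- sin(pi * (b$dur_s - tt[tt > b$dur_s - r]) / (2 * r))^2
      e
    } else {
      sin(pi * tt / b$dur_s)^2
    }
    x[idx] <- x[idx] + b$amp * env * sin(2 * pi * b$freq * tt)
  }
  peg_recording(x / max(abs(x)), sample_rate)
}

# Gaussian blobs in `d` dimensions; returns list(x, labels 0-based).
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(10, 10)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[i, ], "+")))
  list(x = x, labels = rep(0:(k - 1), each = n_per))
}

# --- brute-force validity-index oracles ------------------------------------

silhouette_bf <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(sapply(setdiff(own, i), d, i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(sapply(which(labels == cl), d, i = i)))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

calinski_harabasz_bf <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); ids <- unique(labels); k <- length(ids)
  g <- colMeans(x)
  w <- 0; b <- 0
  for (cl in ids) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    for (r in seq_len(nrow(xi))) w <- w + sum((xi[r, ] - ci)^2)
    b <- b + nrow(xi) * sum((ci - g)^2)
  }
  (b / w) * ((n - k) / (k - 1))
}

davies_bouldin_bf <- function(x, labels) {
  x <- as.matrix(x)
  ids <- sort(unique(labels)); k <- length(ids)
  cent <- lapply(ids, function(cl) colMeans(x[labels == cl, , drop = FALSE]))
  sc <- sapply(seq_len(k), function(j) {
    xi <- x[labels == ids[j], , drop = FALSE]
    mean(apply(xi, 1, function(r) sqrt(sum((r - cent[[j]])^2))))
  })
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (sc[i] + sc[j]) / dij)
    }
    total <- total + best
  }
  total / k
}

# Small synthetic dataset spec for pipeline-level unit tests (cheaper than
# the full default study conditions).
small_synth_spec <- function(seed = 5) {
  synthetic_spec(sample_rate = 8000, duration_s = 60, n_subjects = 2,
                 n_recordings = 1, seed = seed)
}
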