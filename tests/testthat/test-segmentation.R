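# Short-time energy envelope, dynamic thresholding, peak picking,
# proximity filtering, boundary estimation and detection scoring.

test_that("short-time energy matches direct summation", {
  sr <- 1000
  rec <- peg_recording(rep(0.5, 2000), sr)
  env <- short_time_energy(rec, window_s = 0.025, hop_s = 0.005)
  expect_true(all(abs(env$values - 0.25) < 1e-12))
  expect_equal(length(env$values), 1 + (2000 - 25) %/% 5)
  expect_equal(diff(env$frame_times_s), rep(0.005, length(env$values) - 1))

  # silence
  silent <- peg_recording(rep(0, 500), sr)
  expect_true(all(short_time_energy(silent)$values == 0))

  # unit impulse: every covering frame reads 1/W, others 0 (direct oracle)
  x <- rep(0, 400); x[100] <- 1
  rec2 <- peg_recording(x, sr)
  env2 <- short_time_energy(rec2, window_s = 0.025, hop_s = 0.005)
  W <- 25; H <- 5
  oracle <- sapply(seq_along(env2$values), function(i) {
    fr <- x[((i - 1) * H + 1):((i - 1) * H + W)]
    mean(fr^2)
  })
  expect_equal(env2$values, oracle, tolerance = 1e-14)
  expect_true(all(env2$values %in% c(0, 1 / W)))
  expect_error(short_time_energy(peg_recording(rep(0.1, 10), sr)),
               "shorter")
})

test_that("dynamic threshold is mean + 2 population SDs", {
  env <- structure(list(values = rep(3, 10), frame_times_s = 1:10 / 100,
                        window_s = 0.025, hop_s = 0.005, duration_s = 1),
                   class = "peg_envelope")
  expect_equal(dynamic_threshold(env), 3)
  env$values <- c(0, 1)
  expect_equal(dynamic_threshold(env), 1.5)
  set.seed(42)
  env$values <- runif(1e4)
  env$frame_times_s <- seq_along(env$values) / 1000
  expected <- 0.5 + 2 * sqrt(1 / 12)
  se <- 0.5 / sqrt(1e4)  # combined sampling error of mean + 2 SD
  expect_lt(abs(dynamic_threshold(env) - expected), 3 * se)
  env$values <- 1
  expect_error(dynamic_threshold(env), "2 envelope frames")
})

test_that("peak picking respects threshold, ties and file edges", {
  mk_env <- function(v, dur = length(v) * 0.005 + 0.02)
    structure(list(values = v,
                   frame_times_s = 0.0125 + (seq_along(v) - 1) * 0.005,
                   window_s = 0.025, hop_s = 0.005, duration_s = dur),
              class = "peg_envelope")
  flat <- mk_env(rep(1, 100))
  expect_equal(nrow(detect_events(flat, dynamic_threshold(flat))), 0)

  # two equal adjacent super-threshold frames: keep the left one only
  v <- c(rep(0, 50), 5, 5, rep(0, 50))
  ev <- detect_events(mk_env(v), threshold = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time_s, 0.0125 + 50 * 0.005)
  expect_equal(ev$offset_s - ev$onset_s, 0.2)

  # peak too close to the start is dropped (window would cross the edge)
  v2 <- c(rep(0, 5), 5, rep(0, 200))
  expect_equal(nrow(detect_events(mk_env(v2), threshold = 1)), 0)
})

test_that("20 injected bursts at 15 dB SNR are recovered within 100 ms", {
  sr <- 8000
  onsets <- seq(1, 58, length.out = 20)
  bursts <- lapply(onsets, function(o) list(time_s = o, dur_s = 0.1,
                                            freq = 300, amp = 0.8))
  set.seed(10)
  n <- 60 * sr
  x <- rnorm(n, 0, 0)
  rec0 <- make_tone_recording(60, sr, bursts, noise_sd = 0)
  p_sig <- mean(rec0$samples^2)
  noisy <- rec0$samples + rnorm(n, 0, sqrt(p_sig / 10^1.5))
  rec <- peg_recording(noisy / max(abs(noisy)), sr)
  ev <- detect_recording(rec)
  m <- match_events(ev, data.frame(onset_s = onsets, offset_s = onsets + 0.1,
                                   label = ""))
  expect_gte(m$n_matched, 19)
})

test_that("proximity filter resolves conflict chains in both modes", {
  mk <- function(t, e) data.frame(peak_time_s = t, onset_s = t - 0.1,
                                  offset_s = t + 0.1, peak_energy = e)
  close_pair <- mk(c(1.00, 1.05), c(1, 2))
  expect_equal(nrow(proximity_filter(close_pair, mode = "discard")), 0)
  far_pair <- mk(c(1.00, 1.20), c(1, 2))
  expect_equal(nrow(proximity_filter(far_pair, mode = "discard")), 2)
  # keep-strongest on a chain {1.00, 1.05} with energies {2, 3}: keep 1.05
  trio <- mk(c(1.00, 1.05, 1.30), c(2, 3, 1))
  kept <- proximity_filter(trio, mode = "strongest")
  expect_equal(kept$peak_time_s, c(1.05, 1.30))
  expect_error(proximity_filter(mk(c(2, 1), c(1, 1))), "sorted")
})

test_that("filtered events are always pairwise >= 100 ms apart", {
  set.seed(7)
  for (rep_i in 1:25) {
    t <- sort(runif(40, 0, 5))
    ev <- data.frame(peak_time_s = t, onset_s = t - 0.1, offset_s = t + 0.1,
                     peak_energy = runif(40))
    for (mode in c("discard", "strongest")) {
      out <- proximity_filter(ev, mode = mode)
      if (nrow(out) > 1) expect_true(all(diff(out$peak_time_s) >= 0.1))
    }
  }
})

test_that("boundary estimation floors at the window and tracks long events", {
  sr <- 8000
  # isolated 50 ms burst: boundaries collapse to the 200 ms window floor
  rec <- make_tone_recording(10, sr, list(list(time_s = 5, dur_s = 0.05,
                                               freq = 300, amp = 0.9)))
  env <- short_time_energy(rec)
  thr <- dynamic_threshold(env)
  pk <- env$frame_times_s[which.max(env$values)]
  b <- estimate_boundaries(env, pk, thr)
  expect_equal(unname(b[2] - b[1]), 0.2, tolerance = 1e-9)

  # 3 s sustained tone: recovered extent within 2 hops of 3 s
  rec2 <- make_tone_recording(20, sr, list(list(time_s = 8, dur_s = 3,
                                                freq = 200, amp = 0.9,
                                                shape = "flat")))
  env2 <- short_time_energy(rec2)
  thr2 <- dynamic_threshold(env2)
  pk2 <- env2$frame_times_s[which.max(env2$values)]
  b2 <- estimate_boundaries(env2, pk2, thr2)
  expect_lt(abs((b2[2] - b2[1]) - 3), 2 * env2$hop_s + 0.05)

  # symmetric construction gives boundaries symmetric about the peak
  rec3 <- make_tone_recording(10, sr, list(list(time_s = 5, dur_s = 0.4,
                                                freq = 250, amp = 0.9)))
  env3 <- short_time_energy(rec3)
  thr3 <- dynamic_threshold(env3)
  pk3 <- env3$frame_times_s[which.max(env3$values)]
  b3 <- estimate_boundaries(env3, pk3, thr3)
  expect_lt(abs((b3[2] - pk3) - (pk3 - b3[1])), 2 * env3$hop_s + 0.05)

  expect_error(estimate_boundaries(env, 1.0, thr), "not above threshold")
})

test_that("match scoring reproduces the published detector arithmetic", {
  # perfect agreement
  ref <- data.frame(onset_s = c(1, 2, 3), offset_s = c(1.1, 2.1, 3.1),
                    label = "")
  m <- match_events(c(1.01, 2.0, 3.05), ref)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)

  # published arithmetic: 6314 matched of 6435 reference -> recall 98.1%
  expect_equal(round(100 * 6314 / 6435, 1), 98.1)
  # F1 of precision 98.4% and recall 98.1% -> 98.25% (4 dp on proportion)
  p <- 0.984; r <- 0.981
  expect_equal(round(2 * p * r / (p + r), 4), 0.9825)

  # empty inputs give zeros, not NaN
  empty <- match_events(numeric(0), data.frame(onset_s = numeric(0)))
  expect_equal(c(empty$precision, empty$recall, empty$f1), c(0, 0, 0))
})

test_that("matching is symmetric under swapping detected and reference", {
  set.seed(11)
  for (i in 1:20) {
    a <- sort(runif(15, 0, 10)); b <- sort(runif(12, 0, 10))
    m1 <- match_events(a, b)
    m2 <- match_events(b, a)
    expect_equal(m1$n_matched, m2$n_matched)
    expect_equal(m1$precision, m2$recall)
    expect_equal(m1$recall, m2$precision)
  }
})
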