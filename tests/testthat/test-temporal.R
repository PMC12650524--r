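# Event sequences, transition counting/normalization, dwell and gap
# statistics, and the Markov sequence simulator.

mk_events <- function(file, onset, dwell, state) {
  data.frame(file = file, onset_s = onset, offset_s = onset + dwell,
             state = state)
}

test_that("sequences are ordered within files and never interleave", {
  ev <- mk_events(c("a", "a", "b"), c(2, 1, 0.5), 0.1, c(0, 1, 0))
  seqs <- build_sequences(ev, K = 2)
  expect_length(seqs, 2)
  expect_equal(seqs[["a"]]$onset_s, c(1, 2))
  expect_equal(seqs[["a"]]$state, c(1, 0))
  # single-event file contributes no transitions or gaps
  expect_equal(sum(transition_counts(seqs["b"], K = 2)), 0)
  expect_equal(gap_stats(seqs["b"])$n_gaps, 0)
  expect_error(build_sequences(mk_events("a", 1, 0.1, NA)), "labeled")
  expect_error(build_sequences(mk_events("a", 1, -0.5, 0)), "offset_s")
})

test_that("transition counts pool within files only", {
  s1 <- build_sequences(mk_events("f1", 1:4, 0.1, c(0, 1, 1, 0)), K = 2)
  expect_equal(transition_counts(s1), matrix(c(0L, 1L, 1L, 1L), 2,
                                             byrow = TRUE))
  two <- build_sequences(rbind(mk_events("f1", 1:2, 0.1, c(0, 1)),
                               mk_events("f2", 1:2, 0.1, c(1, 0))), K = 2)
  expect_equal(transition_counts(two), matrix(c(0L, 1L, 1L, 0L), 2,
                                              byrow = TRUE))
  empty <- build_sequences(mk_events(character(0), numeric(0), numeric(0),
                                     integer(0)), K = 3)
  expect_equal(transition_counts(empty, K = 3), matrix(0L, 3, 3))
})

test_that("concatenating files equals pooling their count matrices", {
  set.seed(1)
  evA <- mk_events("a", cumsum(runif(20)), 0.1, sample(0:2, 20, TRUE))
  evB <- mk_events("b", cumsum(runif(15)), 0.1, sample(0:2, 15, TRUE))
  NA_ <- transition_counts(build_sequences(evA, K = 3))
  NB <- transition_counts(build_sequences(evB, K = 3))
  Nall <- transition_counts(build_sequences(rbind(evA, evB), K = 3))
  expect_equal(Nall, NA_ + NB)
})

test_that("row normalization follows the epsilon-denominator convention", {
  N <- matrix(0, 5, 5)
  N[1, 1:2] <- 1
  P <- transition_probabilities(N)
  expect_equal(P[1, ], c(0.5, 0.5, 0, 0, 0), tolerance = 1e-8)
  expect_equal(P[2, ], rep(0, 5))               # empty row stays zero
  expect_equal(sum(P[1, ]), 1, tolerance = 1e-6)
  # K = 1 single-row case
  expect_equal(transition_probabilities(matrix(3, 1, 1))[1, 1], 1,
               tolerance = 1e-9)
})

test_that("dwell statistics use the sample SD convention", {
  one <- build_sequences(mk_events("a", 1, 0.2, 0), K = 1)
  d1 <- dwell_stats(one)
  expect_equal(d1$mean_dwell_s, 0.2)
  expect_true(is.na(d1$sd_dwell_s))               # single event: SD undefined
  two <- build_sequences(mk_events("a", c(1, 5), c(1, 3), c(0, 0)), K = 1)
  d2 <- dwell_stats(two)
  expect_equal(d2$mean_dwell_s, 2)
  expect_equal(d2$sd_dwell_s, sqrt(2))            # N-1 denominator
})

test_that("simulated dwell means are recovered within 3 SE", {
  law <- tnorm_law(0.6, 0.14, 0)
  P <- matrix(1, 1, 1)
  sim <- simulate_markov(P, list(law), tnorm_law(0.9, 0.46, 0),
                         n_events = 500, seed = 3)
  seqs <- build_sequences(sim, K = 1)
  d <- dwell_stats(seqs)
  se <- 0.14 / sqrt(500)
  expect_lt(abs(d$mean_dwell_s - tnorm_mean(law)), 3 * se)
})

test_that("gap statistics pool within files and flag negatives", {
  ev <- mk_events("a", c(0, 1.5), c(1, 0.5), c(0, 0))
  g <- gap_stats(build_sequences(ev, K = 1))
  expect_equal(g$mean_gap_s, 0.5)
  expect_equal(g$n_gaps, 1L)
  # overlap produces a negative gap, kept with a warning
  ov <- mk_events("a", c(0, 0.5), c(1, 0.5), c(0, 0))
  expect_warning(gv <- gap_stats(build_sequences(ov, K = 1)), "negative")
  expect_equal(gv$mean_gap_s, -0.5)
  expect_equal(gap_stats(build_sequences(ov, K = 1),
                         drop_negative = TRUE)$n_gaps, 0L)
})

test_that("simulated gap means match the truncated-normal closed form", {
  law <- tnorm_law(0.9, 0.46, 0)
  P <- matrix(1, 1, 1)
  sim <- simulate_markov(P, list(tnorm_law(0.2, 0.05, 0)), law,
                         n_events = 1001, seed = 4)
  g <- gap_stats(build_sequences(sim, K = 1))
  se <- 0.46 / sqrt(1000)
  expect_lt(abs(g$mean_gap_s - tnorm_mean(law)), 3 * se)
})

test_that("the Markov simulator respects its transition law", {
  # absorbing identity chain
  P <- diag(5)
  laws <- default_dwell_laws()
  sim <- simulate_markov(P, laws, tnorm_law(0.9, 0.46, 0), 50,
                         init_state = 0, seed = 5)
  expect_true(all(sim$state == 0))
  # uniform chain: empirical transition matrix within 0.05 max-abs
  Pu <- matrix(1 / 5, 5, 5)
  sim2 <- simulate_markov(Pu, laws, tnorm_law(0.9, 0.46, 0), 5001, seed = 6)
  Phat <- transition_probabilities(
    transition_counts(build_sequences(sim2, K = 5)))
  expect_lt(max(abs(Phat - Pu)), 0.05)
  # seeded determinism
  sim3 <- simulate_markov(Pu, laws, tnorm_law(0.9, 0.46, 0), 100, seed = 7)
  sim4 <- simulate_markov(Pu, laws, tnorm_law(0.9, 0.46, 0), 100, seed = 7)
  expect_identical(sim3, sim4)
  # a reachable non-stochastic row aborts
  Pbad <- diag(5); Pbad[1, 1] <- 0.5
  expect_error(simulate_markov(Pbad, laws, tnorm_law(0.9, 0.46, 0), 10,
                               init_state = 0, seed = 8), "non-stochastic")
})

test_that("timestamps accumulate dwell + gap in simulated sequences", {
  laws <- list(tnorm_law(0.5, 0, 0))
  sim <- simulate_markov(matrix(1, 1, 1), laws, tnorm_law(0.25, 0, 0),
                         n_events = 4, seed = 9)
  expect_equal(sim$onset_s, c(0, 0.75, 1.5, 2.25))
  expect_equal(sim$offset_s - sim$onset_s, rep(0.5, 4))
})

test_that("fit_transition_model conserves transitions and stochasticity", {
  set.seed(10)
  ev <- do.call(rbind, lapply(1:4, function(f)
    mk_events(paste0("f", f), cumsum(runif(30, 0.5, 1.5)), 0.2,
              sample(0:4, 30, TRUE))))
  seqs <- build_sequences(ev, K = 5)
  m <- fit_transition_model(seqs)
  expect_equal(sum(m$counts), 4 * 29)
  rs <- rowSums(m$probabilities)
  has_data <- rowSums(m$counts) > 0
  expect_true(all(abs(rs[has_data] - 1) < 1e-6))
  expect_true(all(rs[!has_data] == 0))
  expect_equal(sum(m$dwell$n_events), nrow(ev))
})
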