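test_that("the five-extremum toy yields the single qualifying turn", {
  # extrema [0, +150, +90, +200, 0]: +90 fails both flanks (60, 110 with the
  # sub-threshold dip absorbed), +150 fails its right flank (the following
  # reversal only reaches 60 uV before the signal exceeds +150 again), +200
  # qualifies on both sides -> exactly one turn, at +200
  x <- toy_signal(c(0, 150, 90, 200, 0))
  d <- detect_turns(x, fs = 1000)
  expect_equal(nrow(d), 1)
  expect_equal(d$amplitude, 200)
  orc <- oracle_turns(x)
  expect_equal(nrow(orc), 1)
  expect_equal(orc$amplitude, 200)
})

test_that("constant and monotone signals contain no turns", {
  expect_equal(nrow(detect_turns(rep(5, 100), fs = 1000)), 0)
  expect_equal(nrow(detect_turns(seq(0, 500, length.out = 100), fs = 1000)), 0)
  expect_error(detect_turns(c(1, 2), fs = 1000), "3 samples")
})

test_that("a 350 Hz triangle of 200 uV peak-to-peak gives 700 turns/s", {
  tri <- make_triangle(350, 14000, 1, amp = 100)
  d <- detect_turns(tri, 14000)
  expect_equal(nrow(d), 700)
  rec <- structure(list(samples = tri, fs = 14000), class = "emg_recording")
  ts <- epoch_turn_frequencies(rec, 0.050)
  expect_true(all(ts$turn_counts == 35))
  expect_true(all(ts$turn_freqs == 700))
  expect_equal(ts$peak_turn_frequency, 700)
})

test_that("scaling below threshold removes all turns; above leaves them", {
  tri <- make_triangle(350, 14000, 0.5, amp = 100)
  expect_equal(nrow(detect_turns(0.49 * tri, 14000)), 0)
  n1 <- nrow(detect_turns(tri, 14000))
  expect_equal(nrow(detect_turns(2.5 * tri, 14000)), n1)
})

test_that("detector agrees with the brute-force oracle on extremum toys", {
  amp_grid <- c(-250, -120, -80, 0, 90, 110, 150, 260)
  set.seed(10)
  for (m in 1:5) {
    for (rep in 1:60) {
      amps <- c(0, sample(amp_grid, m, replace = TRUE), 0)
      x <- toy_signal(amps, per = 6)
      got <- detect_turns(x, fs = 1000)
      want <- oracle_turns(x)
      expect_identical(got$index, as.integer(want$index))
      expect_equal(got$amplitude, want$amplitude)
    }
  }
})

test_that("detector agrees with the oracle on random piecewise signals", {
  set.seed(20)
  for (i in 1:200) {
    x <- random_emg_signal(n_knots = sample(5:30, 1))
    got <- detect_turns(x, fs = 1000)
    want <- oracle_turns(x)
    expect_identical(got$index, as.integer(want$index))
  }
})

test_that("relaxed boundary mode accepts one-flank boundary extrema", {
  # rises to 150 and stays: right flank is the signal boundary
  x <- c(seq(0, 150, length.out = 50), rep(150, 5), seq(150, 140, length.out = 10))
  expect_equal(nrow(detect_turns(x, 1000, boundary = "strict")), 0)
  d <- detect_turns(x, 1000, boundary = "relaxed")
  expect_equal(nrow(d), 1)
  expect_equal(d$amplitude, 150)
})

test_that("epoching assigns turns by time over half-open epochs", {
  fs <- 2000
  silent <- structure(list(samples = rep(0, fs), fs = fs),
                      class = "emg_recording")
  ts <- epoch_turn_frequencies(silent)
  expect_true(all(ts$turn_counts == 0))
  expect_equal(ts$peak_turn_frequency, 0)
  # k turns confined to one epoch
  x <- rep(0, fs)
  x[21:49] <- toy_signal(c(0, 150, -150, 150, 0), per = 7)
  rec <- structure(list(samples = x, fs = fs), class = "emg_recording")
  ts2 <- epoch_turn_frequencies(rec, 0.05)
  k <- sum(ts2$turn_counts)
  expect_gt(k, 0)
  expect_equal(ts2$peak_turn_frequency, k / 0.05)
  expect_equal(sum(ts2$turn_counts > 0), 1)
  # trailing silent padding does not change the peak
  rec_pad <- structure(list(samples = c(x, rep(0, fs)), fs = fs),
                       class = "emg_recording")
  expect_equal(epoch_turn_frequencies(rec_pad, 0.05)$peak_turn_frequency,
               ts2$peak_turn_frequency)
  expect_error(epoch_turn_frequencies(silent, epoch_duration = 2), "epoch")
})

test_that("cohort peak-turn table is keyed by subject and tone", {
  recs <- lapply(1:4, function(tn)
    synthesize_emg(0.5, fs = 5000, turn_rate = 400, subject_id = "S1",
                   tone = tn, seed = tn))
  tab <- cohort_peak_turn_table(recs, groups = c(S1 = "CT-"))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$tone, 1:4)
  expect_true(all(tab$group == "CT-"))
  expect_error(cohort_peak_turn_table(recs[c(1, 1, 2)]), "duplicate")
})
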