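test_that("subthreshold noise alone yields no ground-truth or detected turns", {
  rec <- synthesize_emg(0.5, fs = 5000, turn_rate = 0, noise_amp = 40,
                        seed = 4)
  expect_length(rec$ground_truth$turn_times, 0)
  expect_equal(nrow(detect_turns(rec)), 0)
})

test_that("a 700/s generator places exactly 35 true turns per 50 ms epoch", {
  rec <- synthesize_emg(1, fs = 10000, turn_rate = 700, seed = 2)
  tt <- rec$ground_truth$turn_times
  counts <- table(cut(tt, seq(0, 1, by = 0.05), right = FALSE))
  expect_true(all(counts == 35))
})

test_that("ground truth matches the brute-force rule on the noiseless zig-zag", {
  for (seed in 1:3) {
    rec <- synthesize_emg(0.6, fs = 8000, turn_rate = 300, noise_amp = 0,
                          seed = seed)
    orc <- oracle_turns(rec$samples, 100)
    expect_equal(nrow(orc), length(rec$ground_truth$turn_times))
    # sampled extrema sit within half a sample of the exact knots, so their
    # amplitudes deviate by at most slope / (2 fs)
    expect_equal(sort(orc$amplitude),
                 sort(rec$ground_truth$turn_amplitudes), tolerance = 0.05)
    expect_lt(max(abs((orc$index - 1) / rec$fs -
                        rec$ground_truth$turn_times)), 1 / rec$fs + 1e-9)
  }
})

test_that("noisy synthesis still recovers the exact turn count and times", {
  rec <- synthesize_emg(1, fs = 10000, turn_rate = 600, noise_amp = 40,
                        seed = 11)
  d <- detect_turns(rec)
  expect_equal(nrow(d), length(rec$ground_truth$turn_times))
  expect_lt(max(abs(d$time - rec$ground_truth$turn_times)), 1e-3)
})

test_that("generator preconditions are enforced", {
  expect_error(synthesize_emg(1, turn_rate = 100, amplitude_range = c(90, 200)),
               "100 uV")
  expect_error(synthesize_emg(1, noise_amp = 60), "noise_amp")
  expect_error(synthesize_emg(1, fs = 1000, turn_rate = 600), "sample")
  a <- synthesize_emg(0.2, fs = 4000, turn_rate = 200, seed = 5)
  b <- synthesize_emg(0.2, fs = 4000, turn_rate = 200, seed = 5)
  expect_identical(a$samples, b$samples)
})
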