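test_that("RMS track reproduces closed-form values on simple signals", {
  expect_true(all(compute_energy_track(rep(0.4, 800), fs = 1000)$rms == 0.4))
  expect_true(all(compute_energy_track(rep(-0.4, 800), fs = 1000)$rms == 0.4))
  expect_true(all(compute_energy_track(rep(0, 800), fs = 1000)$rms == 0))
  # sine of amplitude A over frames much longer than the period
  x <- 0.6 * sin(2 * pi * 200 * (0:15999) / 16000)
  en <- compute_energy_track(x, frame_length = 0.1, hop = 0.05, fs = 16000)
  expect_equal(en$rms, rep(0.6 / sqrt(2), length(en$rms)), tolerance = 1e-3)
  expect_equal(unique(round(diff(en$frame_times), 10)), 0.05)
  expect_error(compute_energy_track(rep(0, 10), fs = 16000), "shorter")
  expect_error(compute_energy_track(rep(0, 800), frame_length = 0.001,
                                    hop = 0.005, fs = 1000), "frame_length")
})

test_that("voice bounds recover the constructed onset and offset", {
  ctr <- make_contour(contour_spec(1, 220, duration = 0.8))
  rec <- synthesize_voice(ctr, fs = 16000, noise_rms = 0, lead_silence = 0.3)
  bd <- detect_voice_bounds(compute_energy_track(rec))
  expect_lte(abs(bd$onset - 0.3), 0.0051)       # within one hop
  expect_lte(abs(bd$offset - 1.1), 0.0101)      # within two hops
})

test_that("bound detection tolerates 20 dB SNR within two hops", {
  ctr <- make_contour(contour_spec(2, 204, 244, duration = 0.8))
  rec <- synthesize_voice(ctr, fs = 16000, noise_rms = 0.011, seed = 9,
                          lead_silence = 0.3)
  bd <- detect_voice_bounds(compute_energy_track(rec))
  dur_err <- abs((bd$offset - bd$onset) - 0.8)
  expect_lte(dur_err, 0.0101)
})

test_that("silence raises a no-voice error; zero threshold finds first energy", {
  expect_error(detect_voice_bounds(compute_energy_track(rep(0, 8000),
                                                        fs = 16000)),
               "no voice detected")
  x <- c(rep(0, 1600), rep(0.2, 4800), rep(0, 1600))
  en <- compute_energy_track(x, fs = 16000)
  bd <- detect_voice_bounds(en, threshold_frac = 0)
  first_nonzero <- en$frame_times[which(en$rms > 0)[1]]
  expect_equal(bd$onset, first_nonzero)
})
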