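# unit tests run at 16 kHz to keep FFTs small; the window/zero-pad defaults
# give a bin width of fs / 4096 = 3.9 Hz there

test_that("a level 220 Hz tone with five harmonics is tracked to ~bin accuracy", {
  rec <- synthesize_voice(make_contour(contour_spec(1, 220, duration = 0.8)),
                          fs = 16000, n_harmonics = 5, noise_rms = 0)
  ctr <- analyze_voice(rec)
  expect_gt(sum(ctr$voiced), 100)
  expect_lte(median(abs(ctr$f0[ctr$voiced] - 220)), 2)
})

test_that("a pure sine is tracked at its frequency within one bin", {
  rec <- synthesize_voice(make_contour(contour_spec(1, 300, duration = 0.6)),
                          fs = 16000, n_harmonics = 1, noise_rms = 0)
  ctr <- analyze_voice(rec)
  binw <- attr(ctr, "bin_width")
  expect_lte(max(abs(ctr$f0[ctr$voiced] - 300)), binw)
})

test_that("the falling tone contour is recovered frame-wise within 3 Hz", {
  rec <- synthesize_voice(make_contour(contour_spec(4, 254, 186,
                                                    duration = 0.45)),
                          fs = 16000, noise_rms = 0)
  ctr <- analyze_voice(rec)
  gt <- rec$ground_truth
  truth <- contour_value(gt$spec, ctr$times - gt$onset)
  err <- abs(ctr$f0[ctr$voiced] - truth[ctr$voiced])
  expect_gte(mean(err <= 3), 0.95)
})

test_that("the dipping tone minimum and segment features are recovered", {
  sp <- contour_spec(3, 205, 189, duration = 0.7, f0_min = 170,
                     min_position = 0.6)
  rec <- synthesize_voice(make_contour(sp), fs = 16000, noise_rms = 0)
  ctr <- analyze_voice(rec)
  tf <- extract_tone_features(ctr, 3)
  expect_false(tf$min_at_endpoint)
  expect_equal(tf$f0_min, 170, tolerance = 0.02)
  expect_equal(tf$delta_on_min, -35, tolerance = 3)
  expect_equal(tf$delta_min_off, 19, tolerance = 3)
  expect_equal(tf$slope_on_min * (tf$t_min - ctr$times[ctr$voiced][1]),
               tf$delta_on_min, tolerance = 1e-9)
})

test_that("window longer than the voiced span is an error", {
  rec <- synthesize_voice(make_contour(contour_spec(1, 220, duration = 0.1)),
                          fs = 16000, noise_rms = 0)
  bd <- detect_voice_bounds(compute_energy_track(rec))
  expect_error(estimate_f0_track(rec, bd, window_length = 0.5), "window")
  expect_error(estimate_f0_track(rec, bd, fmin = 300, fmax = 200), "fmin")
})
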