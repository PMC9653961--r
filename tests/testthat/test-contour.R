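test_that("level tone gives a constant contour with zero change", {
  ctr <- make_contour(contour_spec(1, 220, duration = 0.8), hop = 0.005)
  expect_true(all(ctr$f0 == 220))
  tf <- extract_tone_features(ctr, 1)
  expect_equal(tf$delta_on_off, 0)
  expect_equal(tf$slope_on_off, 0)
  expect_equal(tf$max_drop_5ms, 0)
})

test_that("rising tone interpolates linearly between onset and offset", {
  ctr <- make_contour(contour_spec(2, 204, 244, duration = 0.8), hop = 0.005)
  expect_equal(ctr$f0[ctr$times == 0.4], 224)
  expect_equal(ctr$f0[1], 204)
  expect_equal(ctr$f0[length(ctr$f0)], 244)
  expect_true(all(diff(ctr$f0) >= 0))
})

test_that("falling tone per-hop drop equals the closed-form slope", {
  ctr <- make_contour(contour_spec(4, 254, 186, duration = 0.45), hop = 0.005)
  drops <- -diff(ctr$f0)
  expect_equal(drops, rep((254 - 186) / 90, 90))
})

test_that("dipping tone reaches its minimum at min_position and recovers", {
  sp <- contour_spec(3, 205, 189, duration = 0.7, f0_min = 170,
                     min_position = 0.6)
  ctr <- make_contour(sp, hop = 0.005)
  i_min <- which.min(ctr$f0)
  expect_equal(ctr$times[i_min], 0.6 * 0.7, tolerance = 0.005)
  expect_equal(min(ctr$f0), 170)
  expect_equal(ctr$f0[1], 205)
  expect_equal(ctr$f0[length(ctr$f0)], 189)
})

test_that("contour specifications reject shape violations", {
  expect_error(contour_spec(5, 200), "tone")
  expect_error(contour_spec(2, 240, 200), "rising")
  expect_error(contour_spec(4, 200, 240), "falling")
  expect_error(contour_spec(3, 205, 189, f0_min = 200), "f0_min")
  expect_error(contour_spec(3, 205, 189), "f0_min")
  expect_error(contour_spec(3, 205, 189, f0_min = 170, min_position = 1.2),
               "min_position")
  expect_error(make_contour(contour_spec(1, 220), hop = 0), "hop")
})

test_that("cosine easing preserves anchors and monotonicity per segment", {
  sp <- contour_spec(2, 204, 244, duration = 0.8)
  ctr <- make_contour(sp, hop = 0.005, shape = "cosine")
  expect_equal(ctr$f0[1], 204)
  expect_equal(ctr$f0[length(ctr$f0)], 244)
  expect_true(all(diff(ctr$f0) >= 0))
  expect_gt(max(abs(ctr$f0 - make_contour(sp, 0.005)$f0)), 1)
})

test_that("contour_value agrees with make_contour at any sampling", {
  specs <- list(contour_spec(1, 220), contour_spec(2, 204, 244),
                contour_spec(3, 205, 189, f0_min = 170),
                contour_spec(4, 254, 186))
  for (sp in specs) {
    ctr <- make_contour(sp, hop = 0.0025)
    expect_equal(ctr$f0, contour_value(sp, ctr$times))
  }
})
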