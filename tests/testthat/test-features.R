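# build an f0_contour by hand
fake_contour <- function(f0, hop = 0.005, t0 = 0) {
  structure(list(times = t0 + hop * (seq_along(f0) - 1), f0 = f0,
                 voiced = rep(TRUE, length(f0)), hop = hop, spec = NULL),
            class = "f0_contour")
}

test_that("maximal 5 ms drop is the largest consecutive-frame decrease", {
  tf <- extract_tone_features(fake_contour(c(240, 230, 228)), 4)
  expect_equal(tf$max_drop_5ms, 10)
  # monotone non-decreasing contour has zero drop
  tf2 <- extract_tone_features(fake_contour(c(200, 205, 205, 230)), 2)
  expect_equal(tf2$max_drop_5ms, 0)
})

test_that("a linear falling contour's 5 ms drop equals |slope| * 0.005", {
  ctr <- make_contour(contour_spec(4, 254, 186, duration = 0.45), hop = 0.005)
  tf <- extract_tone_features(ctr, 4)
  expect_equal(tf$max_drop_5ms, abs(tf$slope_on_off) * 0.005,
               tolerance = 1e-9)
})

test_that("dipping-tone segments obey the delta/slope identities exactly", {
  ctr <- make_contour(contour_spec(3, 205, 189, duration = 0.7, f0_min = 170,
                                   min_position = 0.6))
  tf <- extract_tone_features(ctr, 3)
  expect_equal(tf$delta_on_min, -35)
  expect_equal(tf$delta_min_off, 19)
  expect_equal(tf$delta_on_off, tf$delta_on_min + tf$delta_min_off)
  expect_equal(tf$slope_on_off * tf$duration, tf$delta_on_off,
               tolerance = 1e-12)
})

test_that("a dipping contour whose minimum sits at an endpoint is flagged", {
  tf <- extract_tone_features(fake_contour(c(170, 180, 200)), 3)
  expect_true(tf$min_at_endpoint)
  expect_true(is.na(tf$f0_min))
  # earliest-minimum tie-break
  tf2 <- extract_tone_features(fake_contour(c(200, 170, 180, 170, 200)), 3)
  expect_equal(tf2$t_min, 0.005)
})

test_that("slope times duration reproduces delta for random contours", {
  set.seed(5)
  for (i in 1:20) {
    f0 <- runif(50, 150, 350)
    tf <- extract_tone_features(fake_contour(f0), sample(1:2, 1))
    expect_equal(tf$slope_on_off * tf$duration, tf$delta_on_off,
                 tolerance = 1e-10)
    expect_gte(tf$max_drop_5ms, 0)
  }
})

test_that("trial averaging is a masked arithmetic mean", {
  ctr <- make_contour(contour_spec(2, 204, 244))
  tf <- extract_tone_features(ctr, 2)
  expect_equal(average_trials(list(tf, tf, tf))$delta_on_off, tf$delta_on_off)
  t1 <- tf; t2 <- tf; t3 <- tf
  t1$delta_on_off <- 30; t2$delta_on_off <- 40; t3$delta_on_off <- 50
  expect_equal(average_trials(list(t1, t2, t3))$delta_on_off, 40)
  t1$f0_onset <- 200; t2$f0_onset <- 210; t3$f0_onset <- 220
  expect_warning(avg2 <- average_trials(list(t1, t3)), "2 trial")
  expect_equal(avg2$f0_onset, 210)
  expect_error(average_trials(list()), "no valid trials")
  t_other <- tf; t_other$tone <- 3L
  expect_error(average_trials(list(tf, t_other)), "different tones")
})

test_that("too few voiced frames is an error", {
  expect_error(extract_tone_features(fake_contour(220), 1), "voiced")
})
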