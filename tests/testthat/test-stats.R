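test_that("pooled-SD Cohen's d reproduces hand-checked values", {
  expect_equal(cohens_d(10, 2, 5, 10, 2, 5)$d, 0)
  # published two-group summaries (17 vs 71): maximal 5 ms drop and peak
  # turn frequency rows
  expect_equal(round(cohens_d(16.1, 5.7, 17, 27.8, 14.8, 71)$d, 2), 0.86)
  expect_equal(round(cohens_d(442.4, 285.0, 17, 730.6, 231.6, 71)$d, 2), 1.19)
  z <- cohens_d(1, 0, 5, 2, 0, 5)
  expect_true(z$infinite)
})

test_that("Cohen's d is symmetric, shift-invariant and scale-homogeneous", {
  set.seed(3)
  for (i in 1:10) {
    m1 <- runif(1, 0, 100); m2 <- runif(1, 0, 100)
    s1 <- runif(1, 1, 30); s2 <- runif(1, 1, 30)
    d0 <- cohens_d(m1, s1, 10, m2, s2, 20)$d
    expect_equal(cohens_d(m2, s2, 20, m1, s1, 10)$d, d0)
    expect_equal(cohens_d(m1 + 7, s1, 10, m2 + 7, s2, 20)$d, d0)
    a <- runif(1, 0.1, 5)
    expect_equal(cohens_d(a * m1, a * s1, 10, a * m2, a * s2, 20)$d, d0)
  }
})

test_that("Student's t matches the reference implementation on raw samples", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.3)
    a <- students_t(x, y)
    b <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$t, unname(b$statistic))
    expect_equal(a$p, b$p.value)
    expect_equal(a$df, unname(b$parameter))
    w <- students_t(x, y, var_equal = FALSE)
    bw <- t.test(x, y)
    expect_equal(w$t, unname(bw$statistic))
    expect_equal(w$p, bw$p.value)
    one <- students_t(x, y, alternative = "less")
    expect_equal(one$p, t.test(x, y, var.equal = TRUE,
                               alternative = "less")$p.value)
  }
})

test_that("summary-statistics route equals the raw-samples route", {
  set.seed(5)
  x <- rnorm(12, 5, 2); y <- rnorm(18, 6, 3)
  a <- students_t(x, y)
  b <- students_t(list(mean = mean(x), sd = sd(x), n = 12),
                  list(mean = mean(y), sd = sd(y), n = 18))
  expect_equal(a$t, b$t, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_equal(students_t(x, x)$t, 0)
  expect_equal(students_t(x, x)$p, 1)
  expect_error(students_t(rep(1, 5), rep(1, 6)), "zero variance")
})

test_that("chi-squared matches the stats engine and flags degeneracies", {
  tab <- matrix(c(7, 10, 47, 24), 2, byrow = TRUE)
  got <- chi_squared(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  prop <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  expect_equal(chi_squared(prop)$statistic, 0)
  expect_equal(chi_squared(prop)$p, 1)
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  expect_warning(chi_squared(matrix(c(1, 9, 2, 8), 2)), "expected")
})

test_that("two-way ICC reproduces frozen reference values on a fixture", {
  X <- matrix(c(210, 214, 208, 233, 229, 236, 190, 195, 188,
                250, 247, 252, 205, 203, 210, 224, 221, 219),
              6, 3, byrow = TRUE)
  # reference values computed with an independent ICC implementation
  expect_equal(icc(X, "A1")$icc, 0.9769826, tolerance = 1e-6)
  expect_equal(icc(X, "C1")$icc, 0.9728257, tolerance = 1e-6)
  expect_equal(icc(X)$cross_trial_sd, 3.1352101, tolerance = 1e-6)
  expect_equal(icc(X)$icc_model, "ICC(A,1)")
})

test_that("duplicated trials give ICC exactly 1 and zero cross-trial SD", {
  v <- c(210, 233, 190, 250)
  X <- cbind(v, v, v)
  r <- icc(X)
  expect_identical(r$icc, 1)
  expect_identical(r$cross_trial_sd, 0)
})

test_that("degenerate and missing-data cases are handled explicitly", {
  r <- icc(matrix(rep(c(5, 6, 7), each = 4), 4, 3))  # identical subjects
  expect_true(r$degenerate)          # no between-subject variance
  expect_true(is.na(r$icc))
  Y <- matrix(rnorm(12, 100, 20), 4, 3)
  Y[2, 3] <- NA
  expect_message(r2 <- icc(Y), "dropped")
  expect_equal(r2$n_subjects, 3)
  expect_error(icc(matrix(1:3, 3, 1)), "2 subjects and 2 trials")
})

test_that("ICC falls toward zero when within-noise dominates", {
  set.seed(6)
  r <- replicate(50, icc(matrix(rnorm(20, 0, 0.5), 20, 3) +
                           matrix(rnorm(60, 0, 20), 20, 3))$icc)
  expect_lt(abs(mean(r)), 0.06)
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_identical(significance_stars(c(0.2, 0.04, 0.004, 0.0004, NA)),
                   c("", "*", "**", "***", ""))
})
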