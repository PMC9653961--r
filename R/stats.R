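#' Pooled-SD Cohen's d from group summary statistics
#'
#' Standardized mean difference d = |m2 - m1| / s_p with the pooled standard
#' deviation s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)). The
#' magnitude is reported (matching the convention of two-group clinical
#' tables); the direction of the difference is kept as metadata.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `d` (magnitude), `s_pooled`, `direction`
#'   (sign of `m2 - m1`), and `infinite` (`TRUE` when the pooled SD is zero
#'   while the means differ).
#' @examples
#' cohens_d(442.4, 285.0, 17, 730.6, 231.6, 71)$d  # 1.19
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    d <- if (m1 == m2) 0 else Inf
    return(list(d = d, s_pooled = 0, direction = sign(m2 - m1),
                infinite = !is.finite(d)))
  }
  list(d = abs(m2 - m1) / sp, s_pooled = sp, direction = sign(m2 - m1),
       infinite = FALSE)
}

#' Two-sample Student's t-test from raw samples or summary statistics
#'
#' Pooled-variance two-sample t by default, computed from either raw sample
#' vectors or `(mean, sd, n)` summaries; both input routes go through the
#' same summary-statistic formula. Welch's unequal-variance variant and
#' one-sided alternatives are available.
#'
#' @param x1,x2 Either numeric sample vectors, or lists/group summaries with
#'   elements `mean`, `sd`, `n`.
#' @param var_equal Pooled variance (`TRUE`, default) or Welch (`FALSE`).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (alternatives refer to `mean(x1) - mean(x2)`).
#' @return List with `t`, `df`, `p`, `mean_diff` (`m1 - m2`).
#' @export
students_t <- function(x1, x2, var_equal = TRUE,
                       alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  s1 <- .summarize_group(x1)
  s2 <- .summarize_group(x2)
  if (s1$n < 2 || s2$n < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (s1$sd == 0 && s2$sd == 0)
    stop("zero variance in both groups", call. = FALSE)
  if (var_equal) {
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    df <- s1$n + s2$n - 2
  } else {
    v1 <- s1$sd^2 / s1$n
    v2 <- s2$sd^2 / s2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  }
  t <- (s1$mean - s2$mean) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p, mean_diff = s1$mean - s2$mean)
}

.summarize_group <- function(x) {
  if (is.numeric(x) && length(x) > 1)
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x)))
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x)))
    return(x[c("mean", "sd", "n")])
  stop("each group must be a sample vector or a list(mean, sd, n)",
       call. = FALSE)
}

#' Pearson chi-squared test for a contingency table
#'
#' Pearson's chi-squared without continuity correction by default (the
#' Yates-corrected variant is available), with the expected counts returned
#' for small-cell diagnostics; a warning is raised when any expected count
#' falls below 5. Rows or columns with zero margins are an error.
#'
#' @param tab A matrix of non-negative counts with at least 2 columns.
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_squared <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), ncol(tab) >= 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  if (any(ct$expected < 5))
    warning("expected count below 5 in some cell; chi-squared approximation is crude")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Intraclass correlation and cross-trial SD for test-retest reliability
#'
#' Single-measure two-way ICC from the mean squares of the subjects-by-
#' trials layout. The default `"A1"` is the two-way absolute-agreement
#' single-measure form ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE +
#' k (MSC - MSE) / n); `"C1"` is the consistency form ICC(3,1) =
#' (MSR - MSE) / (MSR + (k-1) MSE). The cross-trial SD is the mean over
#' subjects of the within-subject SD across trials. Subjects with missing
#' trials are dropped (with a message).
#'
#' @param trials Numeric matrix, subjects in rows, trials in columns
#'   (normally 3).
#' @param model `"A1"` (absolute agreement, default) or `"C1"`
#'   (consistency).
#' @param feature Optional feature name carried into the result.
#' @return An object of class `reliability_result`: `icc`, `icc_model`,
#'   `cross_trial_sd`, `n_subjects`, `n_trials`, and `degenerate` (`TRUE`
#'   with `icc = NA` when there is no between-subject variance).
#' @export
icc <- function(trials, model = c("A1", "C1"), feature = NA_character_) {
  model <- match.arg(model)
  X <- as.matrix(trials)
  complete <- stats::complete.cases(X)
  if (!all(complete)) {
    message(sum(!complete), " subject(s) dropped for missing trials")
    X <- X[complete, , drop = FALSE]
  }
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 trials", call. = FALSE)
  gm <- mean(X)
  rm_ <- rowMeans(X)
  cm <- colMeans(X)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((X - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  cross_sd <- mean(apply(X, 1, stats::sd))
  degenerate <- ssr <= .Machine$double.eps * max(1, sst)
  # exact limit: trials identical within every subject, subjects differ
  if (!degenerate && all(X == X[, 1])) {
    return(structure(list(feature = feature, icc = 1,
                          icc_model = if (model == "A1") "ICC(A,1)" else "ICC(3,1)",
                          cross_trial_sd = 0, n_subjects = n, n_trials = k,
                          degenerate = FALSE),
                     class = "reliability_result"))
  }
  icc_val <- if (degenerate) NA_real_ else if (model == "A1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  structure(list(feature = feature, icc = icc_val,
                 icc_model = if (model == "A1") "ICC(A,1)" else "ICC(3,1)",
                 cross_trial_sd = cross_sd, n_subjects = n, n_trials = k,
                 degenerate = degenerate),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> %s = %.3f, cross-trial SD = %.3g (%d subjects x %d trials)\n",
              x$icc_model, x$icc, x$cross_trial_sd, x$n_subjects, x$n_trials))
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p A p-value (vectorized).
#' @return `""`, `"*"`, `"**"` or `"***"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, "")
}
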