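#' Reference group statistics for the acoustic tone features
#'
#' Per-tone, per-group means and standard deviations of the tone-contour
#' feature set (onset/offset F0, onset-to-offset change and rate, the
#' dipping-tone minimum segments, the maximal 5 ms drop of the falling tone,
#' and phonation duration) for a cohort of female UVFP patients split by
#' cricothyroid involvement (CT+ n = 17, CT- n = 71). These are the default
#' population parameters of [simulate_cohort()].
#'
#' @return A data.frame with columns `tone`, `feature`, `group`, `mean`, `sd`.
#' @export
acoustic_reference <- function() {
  rows <- list(
    # tone, feature, mean+, sd+, mean-, sd-
    list(1L, "onset",         212.3,  41.5, 233.4,  39.3),
    list(1L, "offset",        219.8,  48.6, 236.5,  46.2),
    list(1L, "delta_on_off",    7.5,  22.0,   3.1,  15.8),
    list(1L, "slope_on_off",    8.3,  28.7,   4.3,  22.6),
    list(2L, "onset",         194.1,  38.6, 206.7,  37.1),
    list(2L, "offset",        218.7,  54.1, 250.0,  54.9),
    list(2L, "delta_on_off",   24.6,  23.8,  42.9,  33.3),
    list(2L, "slope_on_off",   30.7,  27.3,  56.6,  44.9),
    list(3L, "onset",         190.5,  39.5, 204.9,  38.0),
    list(3L, "offset",        165.7,  46.2, 188.7,  50.0),
    list(3L, "delta_on_off",  -24.8,  31.5, -16.2,  32.1),
    list(3L, "slope_on_off",  -48.9,  70.0, -33.5,  50.0),
    list(3L, "delta_on_min",  -33.7,  21.6, -34.5,  17.4),
    list(3L, "slope_on_min",  -82.5,  62.2,-105.9,  74.2),
    list(3L, "delta_min_off",   8.9,  16.3,  18.2,  28.8),
    list(3L, "slope_min_off",  20.4,  32.0,  49.1,  66.5),
    list(4L, "onset",         231.0,  51.3, 259.2,  49.6),
    list(4L, "offset",        177.8,  34.0, 188.5,  37.9),
    list(4L, "delta_on_off",  -53.2,  28.3, -70.8,  36.3),
    list(4L, "slope_on_off", -125.9,  68.0,-179.1,  87.0),
    list(4L, "max_drop_5ms",   16.1,   5.7,  27.8,  14.8),
    list(1L, "duration",       0.85,  0.18,  0.81,  0.18),
    list(2L, "duration",       0.87,  0.17,  0.84,  0.17),
    list(3L, "duration",       0.70,  0.17,  0.72,  0.17),
    list(4L, "duration",       0.46,  0.11,  0.45,  0.11))
  m <- do.call(rbind, lapply(rows, function(r)
    data.frame(tone = r[[1]], feature = r[[2]],
               group = c("CT+", "CT-"),
               mean = c(r[[3]], r[[5]]), sd = c(r[[4]], r[[6]]),
               stringsAsFactors = FALSE)))
  rownames(m) <- NULL
  m
}

#' Reference group statistics for lesion-side CT peak turn frequency
#'
#' Per-tone, per-group means and standard deviations (Hz) of the peak
#' 50 ms-epoch turn frequency of the lesion-side cricothyroid muscle.
#' Defaults of the EMG half of [simulate_cohort()].
#'
#' @return A data.frame with columns `tone`, `group`, `mean`, `sd`.
#' @export
turns_reference <- function() {
  d <- data.frame(
    tone  = rep(1:4, each = 2),
    group = rep(c("CT+", "CT-"), 4),
    mean  = c(442.4, 730.6, 439.6, 666.7, 381.6, 594.4, 457.6, 803.0),
    sd    = c(285.0, 231.6, 252.5, 214.3, 263.1, 223.5, 287.5, 233.3),
    stringsAsFactors = FALSE)
  d
}

#' Reference cross-trial standard deviations of the acoustic features
#'
#' Within-subject (trial-to-trial) standard deviations of onset F0,
#' offset F0, onset-to-offset F0 change (Hz), and phonation duration (s) for
#' the three-trial repetition design; used as default within-subject noise by
#' [simulate_cohort()].
#'
#' @return A data.frame with columns `tone`, `feature`, `cross_trial_sd`.
#' @export
reliability_reference <- function() {
  data.frame(
    tone = rep(1:4, each = 4),
    feature = rep(c("onset", "offset", "delta_on_off", "duration"), 4),
    cross_trial_sd = c(9.5, 10.9, 11.3, 0.08,
                       8.7, 14.0, 15.1, 0.08,
                       9.5, 13.3, 16.5, 0.09,
                       12.2, 14.0, 15.7, 0.05),
    stringsAsFactors = FALSE)
}

#' Simulate a two-group cohort of tone features and peak turn frequencies
#'
#' Draws one latent (true) value per subject, tone and feature from the
#' group's Gaussian, then `n_trials` observed trials around it with the
#' feature's within-subject SD, emulating the three-trial test-retest design.
#' Lesion-side CT peak turn frequencies are drawn once per subject and tone.
#'
#' Negative draws of frequency-valued quantities (onset, offset, duration,
#' peak turn frequency) are kept by default (`negative = "allow"`) so that
#' the realized group means and SDs match the requested population
#' parameters exactly in expectation; `negative = "redraw"` resamples them
#' from the positive half of the Gaussian instead (truncation counts are
#' recorded in the `truncations` attribute, and group moments then deviate
#' from the requested parameters wherever the Gaussian has appreciable mass
#' below zero).
#'
#' @param n_ct_pos,n_ct_neg Group sizes (default 17 and 71); both must be
#'   at least 2.
#' @param n_trials Trials per subject for the acoustic features (default 3).
#' @param features Population parameters, as [acoustic_reference()].
#' @param turns Peak-turn-frequency parameters, as [turns_reference()].
#' @param within_sd Within-subject SDs: a data.frame like
#'   [reliability_reference()] (the default), or a single number applied to
#'   every feature. Features absent from the table fall back to
#'   `within_frac` times the group SD.
#' @param within_frac Fallback within-subject SD as a fraction of the group
#'   SD for features without a tabulated cross-trial SD (default 0.3).
#' @param negative `"allow"` (default) or `"redraw"`; see Details.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_cohort`: list with `features` (long
#'   data.frame: `subject_id`, `group`, `tone`, `feature`, `trial`, `value`,
#'   plus the latent `true_value`), `turns` (`subject_id`, `group`, `tone`,
#'   `peak_turn_frequency`), and `manifest` (`subject_id`, `group`).
#' @examples
#' ch <- simulate_cohort(n_ct_pos = 3, n_ct_neg = 4, seed = 1)
#' head(ch$turns)
#' @export
simulate_cohort <- function(n_ct_pos = 17, n_ct_neg = 71, n_trials = 3,
                            features = acoustic_reference(),
                            turns = turns_reference(),
                            within_sd = reliability_reference(),
                            within_frac = 0.3,
                            negative = c("allow", "redraw"), seed = NULL) {
  negative <- match.arg(negative)
  if (n_ct_pos < 2 || n_ct_neg < 2)
    stop("both groups need at least 2 subjects", call. = FALSE)
  stopifnot(all(features$sd >= 0), all(turns$sd >= 0), n_trials >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))

  manifest <- data.frame(
    subject_id = sprintf("P%03d", seq_len(n_ct_pos + n_ct_neg)),
    group = rep(c("CT+", "CT-"), c(n_ct_pos, n_ct_neg)),
    stringsAsFactors = FALSE)

  if (is.numeric(within_sd) && length(within_sd) == 1L) {
    wlookup <- function(tone, feature, gsd) within_sd
  } else {
    wtab <- within_sd
    wlookup <- function(tone, feature, gsd) {
      hit <- wtab$cross_trial_sd[wtab$tone == tone & wtab$feature == feature]
      if (length(hit)) hit[1] else within_frac * gsd
    }
  }

  nonneg_features <- c("onset", "offset", "duration")
  n_trunc <- 0L
  draw <- function(n, mean, sd, enforce_nonneg) {
    x <- stats::rnorm(n, mean, sd)
    if (enforce_nonneg && negative == "redraw" && sd > 0) {
      bad <- which(x < 0)
      while (length(bad)) {
        n_trunc <<- n_trunc + length(bad)
        x[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[x[bad] < 0]
      }
    }
    x
  }

  feat_rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    fr <- features[i, ]
    subj <- manifest$subject_id[manifest$group == fr$group]
    ns <- length(subj)
    true_val <- draw(ns, fr$mean, fr$sd, fr$feature %in% nonneg_features)
    wsd <- wlookup(fr$tone, fr$feature, fr$sd)
    obs <- true_val[rep(seq_len(ns), each = n_trials)] +
      stats::rnorm(ns * n_trials, 0, wsd)
    feat_rows[[i]] <- data.frame(
      subject_id = rep(subj, each = n_trials), group = fr$group,
      tone = fr$tone, feature = fr$feature,
      trial = rep(seq_len(n_trials), ns),
      value = obs, true_value = true_val[rep(seq_len(ns), each = n_trials)],
      stringsAsFactors = FALSE)
  }

  turn_rows <- vector("list", nrow(turns))
  for (i in seq_len(nrow(turns))) {
    tr <- turns[i, ]
    subj <- manifest$subject_id[manifest$group == tr$group]
    turn_rows[[i]] <- data.frame(
      subject_id = subj, group = tr$group, tone = tr$tone,
      peak_turn_frequency = draw(length(subj), tr$mean, tr$sd, TRUE),
      stringsAsFactors = FALSE)
  }

  out <- list(features = do.call(rbind, feat_rows),
              turns = do.call(rbind, turn_rows),
              manifest = manifest)
  attr(out, "truncations") <- n_trunc
  attr(out, "negative") <- negative
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d CT+, %d CT-), %d feature rows, %d turn rows\n",
              nrow(x$manifest), sum(x$manifest$group == "CT+"),
              sum(x$manifest$group == "CT-"), nrow(x$features), nrow(x$turns)))
  invisible(x)
}
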