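# canonical reporting order of the acoustic feature set, per tone
.report_features <- function() {
  list(`1` = c("onset", "offset", "delta_on_off", "slope_on_off"),
       `2` = c("onset", "offset", "delta_on_off", "slope_on_off"),
       `3` = c("onset", "offset", "delta_on_off", "slope_on_off",
               "delta_on_min", "slope_on_min", "delta_min_off",
               "slope_min_off"),
       `4` = c("onset", "offset", "delta_on_off", "slope_on_off",
               "max_drop_5ms"))
}

# features with tabulated test-retest reliability, per tone
.reliability_features <- function() c("onset", "offset", "delta_on_off", "duration")

#' Build the two-group comparison and reliability report
#'
#' Assembles the cohort-level summary tables from a long feature table and a
#' peak-turn-frequency table: per tone and feature, the CT+/CT- group means
#' and SDs of the trial-averaged values, Student's t (pooled, two-sided by
#' default), pooled-SD Cohen's d and significance stars; per tone, the same
#' comparison of the lesion-side peak turn frequency; and per feature, the
#' test-retest reliability (ICC and cross-trial SD) across trials. Subjects
#' with incomplete trial data for a feature are dropped from that feature's
#' reliability row (complete-case analysis); no multiple-testing correction
#' is applied.
#'
#' @param features Long data.frame with columns `subject_id`, `group`,
#'   `tone`, `feature`, `trial`, `value` (as produced by
#'   [simulate_cohort()] or [run_pipeline()]).
#' @param turns Data.frame with columns `subject_id`, `group`, `tone`,
#'   `peak_turn_frequency`, or `NULL` to skip the EMG section.
#' @param var_equal,alternative Passed to [students_t()].
#' @param icc_model Passed to [icc()].
#' @return An object of class `comparison_report`: list with data.frames
#'   `acoustic` (one row per tone x feature: group summaries, `t`, `p`,
#'   `cohens_d`, `stars`), `turns` (one row per tone), and `reliability`
#'   (one row per tone x feature: `mean`, `sd`, `cross_trial_sd`, `icc`).
#' @export
build_comparison_report <- function(features, turns = NULL,
                                    var_equal = TRUE,
                                    alternative = "two.sided",
                                    icc_model = "A1") {
  if (inherits(features, "synthetic_cohort")) {
    if (is.null(turns)) turns <- features$turns
    features <- features$features
  }
  req <- c("subject_id", "group", "tone", "feature", "trial", "value")
  if (!all(req %in% names(features)))
    stop("features table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)

  # trial-averaged value per subject x tone x feature
  avg <- stats::aggregate(value ~ subject_id + group + tone + feature,
                          data = features, FUN = mean)

  order_tab <- .report_features()
  acoustic <- list()
  for (tn in 1:4) {
    for (ft in order_tab[[as.character(tn)]]) {
      sub <- avg[avg$tone == tn & avg$feature == ft, ]
      if (!nrow(sub)) next
      acoustic[[length(acoustic) + 1L]] <- .compare_row(sub$value, sub$group,
                                                       tn, ft, var_equal,
                                                       alternative)
    }
  }
  acoustic <- if (length(acoustic)) do.call(rbind, acoustic) else NULL

  turns_tab <- NULL
  if (!is.null(turns) && nrow(turns)) {
    rows <- lapply(sort(unique(turns$tone)), function(tn) {
      sub <- turns[turns$tone == tn, ]
      .compare_row(sub$peak_turn_frequency, sub$group, tn,
                   "peak_turn_frequency", var_equal, alternative)
    })
    turns_tab <- do.call(rbind, rows)
  }

  reliability <- list()
  for (tn in 1:4) {
    for (ft in .reliability_features()) {
      sub <- features[features$tone == tn & features$feature == ft, ]
      if (!nrow(sub)) next
      M <- .trial_matrix(sub)
      if (is.null(M) || nrow(M) < 2) next
      r <- suppressMessages(icc(M, model = icc_model, feature = ft))
      reliability[[length(reliability) + 1L]] <- data.frame(
        tone = tn, feature = ft,
        mean = mean(M), sd = stats::sd(rowMeans(M)),
        cross_trial_sd = r$cross_trial_sd, icc = r$icc,
        icc_model = r$icc_model, n_subjects = r$n_subjects,
        stringsAsFactors = FALSE)
    }
  }
  reliability <- if (length(reliability)) do.call(rbind, reliability) else NULL

  structure(list(acoustic = acoustic, turns = turns_tab,
                 reliability = reliability,
                 settings = list(var_equal = var_equal,
                                 alternative = alternative,
                                 icc_model = icc_model,
                                 multiple_testing = "none")),
            class = "comparison_report")
}

.compare_row <- function(values, groups, tone, feature, var_equal,
                         alternative) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  g1 <- values[groups == "CT+"]
  g2 <- values[groups == "CT-"]
  if (length(g1) < 2 || length(g2) < 2)
    stop(sprintf("group with n < 2 for tone %d feature %s", tone, feature),
         call. = FALSE)
  tt <- students_t(g1, g2, var_equal = var_equal, alternative = alternative)
  d <- cohens_d(mean(g1), stats::sd(g1), length(g1),
                mean(g2), stats::sd(g2), length(g2))
  data.frame(tone = tone, feature = feature,
             n_ct_pos = length(g1), mean_ct_pos = mean(g1),
             sd_ct_pos = stats::sd(g1),
             n_ct_neg = length(g2), mean_ct_neg = mean(g2),
             sd_ct_neg = stats::sd(g2),
             t = tt$t, p = tt$p, cohens_d = d$d,
             stars = significance_stars(tt$p),
             stringsAsFactors = FALSE)
}

# subjects x trials matrix for one tone x feature slice (complete cases)
.trial_matrix <- function(sub) {
  trials <- sort(unique(sub$trial))
  if (length(trials) < 2) return(NULL)
  w <- stats::reshape(sub[, c("subject_id", "trial", "value")],
                      idvar = "subject_id", timevar = "trial",
                      direction = "wide")
  M <- as.matrix(w[, -1, drop = FALSE])
  rownames(M) <- w$subject_id
  M[stats::complete.cases(M), , drop = FALSE]
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  if (!is.null(x$acoustic)) {
    cat(sprintf("  acoustic: %d feature rows across %d tones\n",
                nrow(x$acoustic), length(unique(x$acoustic$tone))))
  }
  if (!is.null(x$turns))
    cat(sprintf("  turns: %d tone rows\n", nrow(x$turns)))
  if (!is.null(x$reliability))
    cat(sprintf("  reliability: %d rows\n", nrow(x$reliability)))
  cat(sprintf("  t-test: %s, %s; ICC: %s; multiple testing: %s\n",
              if (x$settings$var_equal) "pooled" else "Welch",
              x$settings$alternative, x$settings$icc_model,
              x$settings$multiple_testing))
  invisible(x)
}
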