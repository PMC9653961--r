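#' Extract the tone-contour feature set from an F0 track
#'
#' Reads F0 at the first and last voiced frames (the ON and OFF points),
#' computes the onset-to-offset change `delta_on_off`, its rate
#' `slope_on_off` (change divided by segment duration), the phonation
#' duration, and the maximal F0 drop between consecutive frames
#' (`max_drop_5ms` at the default 5 ms hop, floored at zero). For the
#' dipping tone (tone 3) the global contour minimum strictly between ON and
#' OFF defines the MIN point and the two extra segments ON-MIN and MIN-OFF
#' with their changes and rates; an earliest-minimum tie-break applies, and
#' a minimum lying at an endpoint leaves the MIN features `NA` with
#' `min_at_endpoint = TRUE`.
#'
#' All features are computed for every tone; which ones are scientifically
#' meaningful per tone (levelness for tone 1, rise for tone 2, dip segments
#' for tone 3, fall and 5 ms drop for tone 4) is a reporting decision made
#' by [build_comparison_report()].
#'
#' @param contour An `f0_contour` (from [estimate_f0_track()] or
#'   [make_contour()]).
#' @param tone Tone label 1--4; defaults to the contour's generating spec
#'   when present.
#' @return An object of class `tone_features` (a named list of scalars):
#'   `tone`, `f0_onset`, `f0_offset`, `f0_min`, `t_min`, `delta_on_off`,
#'   `delta_on_min`, `delta_min_off`, `slope_on_off`, `slope_on_min`,
#'   `slope_min_off`, `max_drop_5ms`, `duration`, `min_at_endpoint`.
#' @export
extract_tone_features <- function(contour, tone = NULL) {
  stopifnot(inherits(contour, "f0_contour"))
  if (is.null(tone)) {
    if (is.null(contour$spec)) stop("'tone' required", call. = FALSE)
    tone <- contour$spec$tone
  }
  if (!(length(tone) == 1L && tone %in% 1:4))
    stop("'tone' must be one of 1, 2, 3, 4", call. = FALSE)
  v <- which(contour$voiced & !is.na(contour$f0))
  if (length(v) < 2)
    stop("need at least 2 voiced frames", call. = FALSE)
  f0 <- contour$f0[v]
  tt <- contour$times[v]
  n <- length(v)

  f0_onset <- f0[1]; f0_offset <- f0[n]
  duration <- tt[n] - tt[1]
  delta_on_off <- f0_offset - f0_onset
  slope_on_off <- delta_on_off / duration
  drops <- f0[-n] - f0[-1]
  max_drop <- max(0, drops)

  f0_min <- NA_real_; t_min <- NA_real_
  delta_on_min <- NA_real_; delta_min_off <- NA_real_
  slope_on_min <- NA_real_; slope_min_off <- NA_real_
  min_at_endpoint <- FALSE
  if (tone == 3L) {
    i_min <- which.min(f0)                       # earliest global minimum
    if (i_min == 1L || i_min == n) {
      min_at_endpoint <- TRUE
    } else {
      f0_min <- f0[i_min]; t_min <- tt[i_min]
      delta_on_min <- f0_min - f0_onset
      delta_min_off <- f0_offset - f0_min
      slope_on_min <- delta_on_min / (t_min - tt[1])
      slope_min_off <- delta_min_off / (tt[n] - t_min)
    }
  }

  structure(list(tone = as.integer(tone), f0_onset = f0_onset,
                 f0_offset = f0_offset, f0_min = f0_min, t_min = t_min,
                 delta_on_off = delta_on_off, delta_on_min = delta_on_min,
                 delta_min_off = delta_min_off, slope_on_off = slope_on_off,
                 slope_on_min = slope_on_min, slope_min_off = slope_min_off,
                 max_drop_5ms = max_drop, duration = duration,
                 min_at_endpoint = min_at_endpoint),
            class = "tone_features")
}

#' Average tone features over repeated trials
#'
#' Arithmetic mean of every scalar feature over the trials of one subject
#' and tone. Invalid or missing trials (`NULL` entries) are dropped with a
#' warning; features that are `NA` in some trials are averaged over the
#' trials where they are defined.
#'
#' @param features A list of `tone_features`, normally of length 3.
#' @return A single `tone_features` with the per-field means.
#' @export
average_trials <- function(features) {
  features <- Filter(Negate(is.null), features)
  if (!length(features)) stop("no valid trials to average", call. = FALSE)
  stopifnot(all(vapply(features, inherits, TRUE, "tone_features")))
  tones <- vapply(features, function(f) f$tone, 0L)
  if (length(unique(tones)) != 1L)
    stop("trials come from different tones", call. = FALSE)
  if (length(features) < 3)
    warning(sprintf("averaging %d trial(s) instead of 3", length(features)))
  fields <- c("f0_onset", "f0_offset", "f0_min", "t_min", "delta_on_off",
              "delta_on_min", "delta_min_off", "slope_on_off",
              "slope_on_min", "slope_min_off", "max_drop_5ms", "duration")
  out <- features[[1]]
  for (f in fields) {
    vals <- vapply(features, function(x) as.numeric(x[[f]]), 0)
    out[[f]] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  out$min_at_endpoint <- any(vapply(features, function(x) x$min_at_endpoint, TRUE))
  out
}

#' @export
print.tone_features <- function(x, ...) {
  cat(sprintf("<tone_features> tone %d: ON %.1f Hz, OFF %.1f Hz, dF0 %.1f Hz over %.2f s\n",
              x$tone, x$f0_onset, x$f0_offset, x$delta_on_off, x$duration))
  invisible(x)
}

#' @export
as.data.frame.tone_features <- function(x, ...) {
  data.frame(tone = x$tone, f0_onset = x$f0_onset, f0_offset = x$f0_offset,
             f0_min = x$f0_min, t_min = x$t_min,
             delta_on_off = x$delta_on_off, delta_on_min = x$delta_on_min,
             delta_min_off = x$delta_min_off, slope_on_off = x$slope_on_off,
             slope_on_min = x$slope_on_min, slope_min_off = x$slope_min_off,
             max_drop_5ms = x$max_drop_5ms, duration = x$duration,
             min_at_endpoint = x$min_at_endpoint)
}

#' Resample a voiced contour onto a normalized 0..1 time grid
#'
#' Linearly interpolates the voiced part of an F0 track onto `n_grid`
#' equally spaced points of normalized time, so that contours of different
#' durations can be averaged across subjects. Grid point 0 carries the onset
#' F0 and grid point 1 the offset F0.
#'
#' @param contour An `f0_contour`.
#' @param n_grid Number of grid points (default 101).
#' @return An object of class `normalized_contour`: `grid`, `f0`.
#' @export
normalize_contour <- function(contour, n_grid = 101) {
  stopifnot(inherits(contour, "f0_contour"), n_grid >= 2)
  v <- which(contour$voiced & !is.na(contour$f0))
  if (length(v) < 2) stop("need at least 2 voiced frames", call. = FALSE)
  tt <- contour$times[v]
  u <- (tt - tt[1]) / (tt[length(tt)] - tt[1])
  grid <- seq(0, 1, length.out = n_grid)
  structure(list(grid = grid,
                 f0 = stats::approx(u, contour$f0[v], xout = grid)$y),
            class = "normalized_contour")
}

#' Group mean and SEM band over normalized contours
#'
#' Pointwise mean and standard error of the mean across subjects on the
#' shared normalized-time grid; the SEM is the half-width of the group band
#' in population contour plots.
#'
#' @param contours A non-empty list of `normalized_contour` objects on the
#'   same grid.
#' @return An object of class `normalized_contour` with `grid`, `f0_mean`,
#'   `f0_sem` (0 with attribute `n1 = TRUE` when only one subject), and `n`.
#' @export
aggregate_band <- function(contours) {
  if (!length(contours)) stop("empty group", call. = FALSE)
  stopifnot(all(vapply(contours, inherits, TRUE, "normalized_contour")))
  grid <- contours[[1]]$grid
  if (!all(vapply(contours, function(cc) length(cc$grid) == length(grid), TRUE)))
    stop("contours are on different grids", call. = FALSE)
  m <- do.call(rbind, lapply(contours, function(cc) cc$f0))
  n <- nrow(m)
  f0_mean <- colMeans(m)
  f0_sem <- if (n > 1) apply(m, 2, stats::sd) / sqrt(n) else rep(0, ncol(m))
  out <- structure(list(grid = grid, f0_mean = f0_mean, f0_sem = f0_sem,
                        n = n),
                   class = "normalized_contour")
  if (n == 1) attr(out, "n1") <- TRUE
  out
}
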