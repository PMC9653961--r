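#' Detect EMG turns under the two-sided 100 uV rule
#'
#' A turn is a change of waveform polarity with an amplitude excursion of at
#' least `amp_threshold` (default 100 uV) both before and after the change;
#' sub-threshold wiggles neither count as turns nor interrupt a larger
#' monotone excursion. Operationally this is sequential (Willison-style)
#' turns counting: excursions are measured between consecutive qualifying
#' turning points, the reference for the first turn being the signal's
#' starting value. Candidate turning points are local extrema (sign changes
#' of the first difference, plateaus collapsed to their first sample); the
#' boundary samples serve as flank references for the first and last
#' extremum. With `boundary = "strict"` (default) both flanks must reach the
#' threshold; `boundary = "relaxed"` waives the requirement on the side that
#' ends at a signal boundary.
#'
#' @param samples Numeric waveform in uV (or an `emg_recording`).
#' @param fs Sampling rate in Hz (taken from the recording if one is given).
#' @param amp_threshold Minimum excursion on both sides of a turn, uV
#'   (default 100).
#' @param boundary `"strict"` (default) or `"relaxed"`; see Details.
#' @return A data.frame with one row per qualifying turn: `time` (s),
#'   `amplitude` (uV), `index` (sample). Zero rows when no turn qualifies.
#' @examples
#' x <- c(0, 150, 90, 200, 0)
#' detect_turns(x, fs = 1)
#' @export
detect_turns <- function(samples, fs = NULL, amp_threshold = 100,
                         boundary = c("strict", "relaxed")) {
  boundary <- match.arg(boundary)
  if (inherits(samples, "emg_recording")) {
    fs <- samples$fs
    samples <- samples$samples
  }
  if (is.null(fs)) stop("'fs' required", call. = FALSE)
  if (length(samples) < 3)
    stop("need at least 3 samples", call. = FALSE)
  x <- as.numeric(samples)
  n <- length(x)

  # candidate extrema with plateau collapse: keep runs of nonzero slope
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(.turns_df(integer(0), numeric(0), fs))
  s <- sign(d[nz])
  flip <- which(s[-1] != s[-length(s)])
  cand <- nz[flip] + 1L            # first sample of each extremum/plateau
  if (!length(cand)) return(.turns_df(integer(0), numeric(0), fs))
  v <- x[cand]

  # sequential qualification. Phase 1 (no reversal confirmed yet): track the
  # running maximum and minimum over the candidates; the first excursion of
  # amp_threshold away from one of them confirms a reversal there, which is
  # a turn only if it also lies amp_threshold from the starting value (the
  # left-flank rule for the first extremum). Phase 2: track the running
  # extreme in the current direction; each counter-movement reaching
  # amp_threshold confirms a turn at that extreme (its left flank to the
  # previous reversal point is at least amp_threshold by construction).
  m <- length(cand)
  keep <- logical(m)
  vals_ext <- c(v, x[n])            # boundary value closes the last reversal
  dirn <- 0L
  best <- 0L
  mxv <- x[1]; mxi <- 0L            # index 0 = the signal start
  mnv <- x[1]; mni <- 0L
  i <- 1L
  while (i <= m + 1L && dirn == 0L) {
    vi <- vals_ext[i]
    if (vi > mxv) { mxv <- vi; mxi <- i }
    if (vi < mnv) { mnv <- vi; mni <- i }
    if (vi - mnv >= amp_threshold) {
      if (mni >= 1L && mni <= m &&
          (abs(mnv - x[1]) >= amp_threshold || boundary == "relaxed"))
        keep[mni] <- TRUE
      dirn <- 1L; best <- i
    } else if (mxv - vi >= amp_threshold) {
      if (mxi >= 1L && mxi <= m &&
          (abs(mxv - x[1]) >= amp_threshold || boundary == "relaxed"))
        keep[mxi] <- TRUE
      dirn <- -1L; best <- i
    }
    i <- i + 1L
  }
  while (i <= m + 1L) {
    vi <- vals_ext[i]
    if ((vi - vals_ext[best]) * dirn > 0) {   # same direction, more extreme
      best <- i
    } else if (abs(vals_ext[best] - vi) >= amp_threshold) {
      if (best <= m) keep[best] <- TRUE
      dirn <- -dirn
      best <- i
    } else if (i == m + 1L && boundary == "relaxed" && best >= 1L &&
               best <= m) {
      keep[best] <- TRUE          # right flank ends at the signal boundary
    }
    i <- i + 1L
  }
  .turns_df(cand[keep], v[keep], fs)
}

.turns_df <- function(idx, amp, fs) {
  data.frame(time = (idx - 1) / fs, amplitude = amp, index = idx)
}

#' Per-epoch turn frequencies and the peak turn frequency
#'
#' Bins a raw EMG recording into non-overlapping epochs (default 50 ms,
#' aligned to the start of the recording; a trailing partial epoch is
#' discarded), counts qualifying turns per epoch by turn time over the
#' half-open interval `[start, start + epoch)`, and converts counts to
#' frequencies. The peak turn frequency is the maximum epoch turn frequency
#' of the recording.
#'
#' @param rec An `emg_recording`.
#' @param epoch_duration Epoch length in seconds (default 0.050).
#' @param amp_threshold,boundary Passed to [detect_turns()].
#' @return An object of class `turn_series`: `epoch_starts` (s),
#'   `turn_counts`, `turn_freqs` (Hz), `epoch_duration`,
#'   `peak_turn_frequency` (Hz).
#' @export
epoch_turn_frequencies <- function(rec, epoch_duration = 0.050,
                                   amp_threshold = 100,
                                   boundary = "strict") {
  stopifnot(inherits(rec, "emg_recording"), epoch_duration > 0)
  dur <- length(rec$samples) / rec$fs
  n_epochs <- floor(dur / epoch_duration + 1e-9)
  if (n_epochs < 1)
    stop("recording shorter than one epoch", call. = FALSE)
  turns <- detect_turns(rec$samples, rec$fs, amp_threshold, boundary)
  epoch_starts <- (seq_len(n_epochs) - 1) * epoch_duration
  idx <- findInterval(turns$time, c(epoch_starts, n_epochs * epoch_duration),
                      left.open = FALSE, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= n_epochs &
               turns$time < n_epochs * epoch_duration]
  counts <- tabulate(idx, nbins = n_epochs)
  freqs <- counts / epoch_duration
  structure(list(epoch_starts = epoch_starts, turn_counts = counts,
                 turn_freqs = freqs, epoch_duration = epoch_duration,
                 peak_turn_frequency = max(freqs)),
            class = "turn_series")
}

#' @export
print.turn_series <- function(x, ...) {
  cat(sprintf("<turn_series> %d epochs of %.0f ms, %d turns, peak %.0f Hz\n",
              length(x$epoch_starts), 1000 * x$epoch_duration,
              sum(x$turn_counts), x$peak_turn_frequency))
  invisible(x)
}

#' Cohort table of per-subject, per-tone peak turn frequencies
#'
#' Runs the epoch/turns analysis over a set of lesion-side CT recordings and
#' assembles the long-format table that feeds the group comparison. Missing
#' subject-tone recordings yield no row (and a message); duplicate
#' subject-tone recordings are an error.
#'
#' @param recordings A list of `emg_recording` objects with `subject_id` and
#'   `tone` set.
#' @param groups Named character vector mapping subject id to group label
#'   (optional; `NA` group otherwise).
#' @param epoch_duration,amp_threshold Analysis parameters.
#' @return A data.frame: `subject_id`, `group`, `tone`,
#'   `peak_turn_frequency`.
#' @export
cohort_peak_turn_table <- function(recordings, groups = NULL,
                                   epoch_duration = 0.050,
                                   amp_threshold = 100) {
  stopifnot(length(recordings) >= 1,
            all(vapply(recordings, inherits, TRUE, "emg_recording")))
  rows <- lapply(recordings, function(r) {
    ts <- epoch_turn_frequencies(r, epoch_duration, amp_threshold)
    data.frame(subject_id = r$subject_id,
               group = if (!is.null(groups)) unname(groups[r$subject_id]) else NA_character_,
               tone = r$tone,
               peak_turn_frequency = ts$peak_turn_frequency,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$subject_id, out$tone)
  if (anyDuplicated(key))
    stop("duplicate subject x tone EMG recordings: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  out
}
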