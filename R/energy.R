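#' Short-time RMS energy track of a voice recording
#'
#' Frames the waveform into `frame_length`-second windows stepped every
#' `hop` seconds (frames aligned to their start sample, trailing partial
#' frame dropped) and computes the root-mean-square amplitude of each frame.
#'
#' @param rec A `voice_recording`, or a plain numeric vector together with
#'   `fs`.
#' @param frame_length Frame length in seconds (default 0.010).
#' @param hop Frame step in seconds (default 0.005); must not exceed
#'   `frame_length`.
#' @param fs Sampling rate, required when `rec` is a bare numeric vector.
#' @return An object of class `energy_track`: `frame_times` (frame start
#'   times, s), `rms`, `frame_length`, `hop`.
#' @export
compute_energy_track <- function(rec, frame_length = 0.010, hop = 0.005,
                                 fs = NULL) {
  if (inherits(rec, "voice_recording")) {
    x <- rec$samples; fs <- rec$fs
  } else {
    x <- rec
    if (is.null(fs)) stop("'fs' required for a bare sample vector", call. = FALSE)
  }
  if (!(hop > 0 && frame_length >= hop))
    stop("need frame_length >= hop > 0", call. = FALSE)
  L <- round(frame_length * fs)
  H <- round(hop * fs)
  if (length(x) < L)
    stop("recording shorter than one frame", call. = FALSE)
  n_frames <- floor((length(x) - L) / H) + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  rms <- vapply(starts, function(s) sqrt(mean(x[(s + 1):(s + L)]^2)), 0)
  structure(list(frame_times = starts / fs, rms = rms,
                 frame_length = frame_length, hop = hop),
            class = "energy_track")
}

#' Detect voice onset and offset from an energy track
#'
#' The beginning of the voice is an abrupt increase in RMS energy above a
#' threshold placed `threshold_frac` of the way from the baseline (the
#' median RMS of the leading-silence frames) to the peak RMS; the ending is
#' the return of energy to baseline. Only above-threshold runs lasting at
#' least `min_voiced` seconds count, which rejects clicks.
#'
#' @param energy An `energy_track` from [compute_energy_track()].
#' @param threshold_frac Fraction of the baseline-to-peak RMS span used as
#'   the detection threshold (default 0.1).
#' @param min_voiced Minimum duration a run must stay above threshold, in
#'   seconds (default 0.05).
#' @return An object of class `voice_bounds`: `onset`, `offset` (seconds).
#'   Errors with "no voice detected" when no qualifying run exists.
#' @export
detect_voice_bounds <- function(energy, threshold_frac = 0.1,
                                min_voiced = 0.05) {
  stopifnot(inherits(energy, "energy_track"))
  rms <- energy$rms
  if (!length(rms)) stop("empty energy track", call. = FALSE)
  peak <- max(rms)
  # leading-silence estimate: frames before the first frame above half peak
  first_loud <- which(rms > 0.5 * peak)[1]
  baseline <- if (!is.na(first_loud) && first_loud > 1)
    stats::median(rms[seq_len(first_loud - 1)]) else 0
  thr <- baseline + threshold_frac * (peak - baseline)
  above <- rms > thr & rms > 0
  if (!any(above)) stop("no voice detected", call. = FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths * energy$hop >= min_voiced)
  if (!any(ok)) stop("no voice detected", call. = FALSE)
  i1 <- starts[which(ok)[1]]
  i2 <- ends[utils::tail(which(ok), 1)]
  structure(list(onset = energy$frame_times[i1],
                 offset = energy$frame_times[i2] + energy$frame_length,
                 threshold = thr, baseline = baseline),
            class = "voice_bounds")
}

#' @export
print.voice_bounds <- function(x, ...) {
  cat(sprintf("<voice_bounds> onset %.3f s, offset %.3f s (duration %.3f s)\n",
              x$onset, x$offset, x$offset - x$onset))
  invisible(x)
}
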