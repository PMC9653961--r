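#' Synthesize a laryngeal EMG interference pattern with known turns
#'
#' Generates a piecewise-linear zig-zag through alternating positive and
#' negative extrema placed uniformly at `turn_rate` per second, with extremum
#' magnitudes drawn uniformly from `amplitude_range`, plus uniform noise of
#' amplitude `noise_amp`. Because the extremum magnitudes exceed the 100 uV
#' turn threshold and the noise peak-to-peak stays below it, every placed
#' extremum is a qualifying turn and the noise can neither add nor remove
#' turns; the generator therefore knows the exact turn times and amplitudes.
#'
#' @param duration Signal duration in seconds.
#' @param fs Sampling rate in Hz (default 10000).
#' @param turn_rate Placed extrema per second (0 gives pure noise).
#' @param amplitude_range Length-2 vector, uniform range of extremum
#'   magnitudes in uV; minimum must exceed 100 uV.
#' @param noise_amp Half peak-to-peak amplitude of uniform noise in uV; must
#'   be below 50 uV so that noise excursions stay under the turn threshold.
#' @param subject_id,muscle,side,tone Identity labels.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return An object of class `emg_recording`: `samples` (uV), `fs`, labels,
#'   and `ground_truth` (list with `turn_times`, `turn_amplitudes`).
#' @examples
#' rec <- synthesize_emg(0.5, fs = 5000, turn_rate = 400, seed = 1)
#' length(rec$ground_truth$turn_times)
#' @export
synthesize_emg <- function(duration = 1, fs = 10000, turn_rate = 600,
                           amplitude_range = c(120, 600), noise_amp = 30,
                           subject_id = NA_character_, muscle = "CT",
                           side = "lesion", tone = NA_integer_, seed = NULL) {
  stopifnot(duration > 0, fs > 0, turn_rate >= 0, length(amplitude_range) == 2)
  if (turn_rate > 0 && amplitude_range[1] <= 100)
    stop("amplitude_range minimum must exceed 100 uV (the turn threshold)",
         call. = FALSE)
  if (noise_amp >= 50)
    stop("noise_amp must be below 50 uV so noise cannot create turns",
         call. = FALSE)
  if (turn_rate >= fs / 2)
    stop("turn_rate too high: successive extrema would fall within one sample",
         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  n_turns <- floor(duration * turn_rate)
  if (n_turns > 0) {
    turn_times <- (seq_len(n_turns) - 0.5) / turn_rate
    mags <- stats::runif(n_turns, amplitude_range[1], amplitude_range[2])
    signs <- rep_len(c(1, -1), n_turns)
    turn_amps <- mags * signs
    knots_t <- c(0, turn_times, duration)
    knots_v <- c(0, turn_amps, 0)
    x <- stats::approx(knots_t, knots_v, xout = t)$y
  } else {
    turn_times <- numeric(0)
    turn_amps <- numeric(0)
    x <- rep(0, n)
  }
  if (noise_amp > 0) x <- x + stats::runif(n, -noise_amp, noise_amp)

  gt <- list(turn_times = turn_times, turn_amplitudes = turn_amps)
  structure(list(samples = x, fs = fs, subject_id = subject_id,
                 muscle = muscle, side = side, tone = tone,
                 ground_truth = gt),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %.2f s @ %g Hz, %s/%s, subject %s tone %s\n",
              length(x$samples) / x$fs, x$fs, x$muscle, x$side,
              x$subject_id, x$tone))
  invisible(x)
}
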