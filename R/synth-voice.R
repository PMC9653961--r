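#' Synthesize a harmonic voice signal carrying a known F0 contour
#'
#' Builds a voiced-bilabial-nasal-like stand-in: a sum of `n_harmonics`
#' sinusoids locked to the instantaneous F0 (phase is the running integral of
#' the contour), with harmonic amplitudes decaying as 1/k, shaped by a linear
#' attack/release energy envelope, padded with lead and tail silence, and
#' optionally overlaid with Gaussian noise. The exact onset/offset times and
#' the generating contour are returned as ground truth, which is what makes
#' the downstream analyzer testable.
#'
#' @param contour An `f0_contour` from [make_contour()].
#' @param fs Sampling rate in Hz (default 44100).
#' @param n_harmonics Number of harmonics (default 5). `n_harmonics *
#'   max(F0)` must stay below the Nyquist frequency.
#' @param amp Peak amplitude of the voiced span (waveform units, default 0.3).
#' @param env_attack,env_release Linear attack / release ramp durations in
#'   seconds (defaults 0.02 and 0.05); the remainder of the phonation is
#'   sustained at full amplitude.
#' @param noise_rms RMS of additive Gaussian noise over the whole file
#'   (default 0 = noiseless).
#' @param lead_silence,tail_silence Silence padding in seconds (defaults 0.3
#'   and 0.2).
#' @param harmonic_decay Exponent of the harmonic roll-off; amplitude of
#'   harmonic k is proportional to 1/k^harmonic_decay (default 1).
#' @param subject_id,tone,trial Identity labels attached to the recording.
#' @param seed Optional integer seed controlling the noise draw; fixed seed
#'   gives a byte-identical waveform.
#' @return An object of class `voice_recording`: `samples`, `fs`, identity
#'   labels, and `ground_truth` (list with `onset`, `offset`, `contour`,
#'   `spec`).
#' @examples
#' ctr <- make_contour(contour_spec(1, 220), hop = 0.005)
#' rec <- synthesize_voice(ctr, fs = 16000, n_harmonics = 1, noise_rms = 0)
#' rec$ground_truth$onset
#' @export
synthesize_voice <- function(contour, fs = 44100, n_harmonics = 5, amp = 0.3,
                             env_attack = 0.02, env_release = 0.05,
                             noise_rms = 0, lead_silence = 0.3,
                             tail_silence = 0.2, harmonic_decay = 1,
                             subject_id = NA_character_, tone = NULL,
                             trial = NA_integer_, seed = NULL) {
  stopifnot(inherits(contour, "f0_contour"), fs > 0, n_harmonics >= 1)
  if (is.null(tone)) tone <- if (!is.null(contour$spec)) contour$spec$tone else NA_integer_
  dur <- max(contour$times)
  if (n_harmonics * max(contour$f0) >= fs / 2)
    stop(sprintf("Nyquist violated: %d harmonics x %.0f Hz >= fs/2 = %.0f Hz",
                 n_harmonics, max(contour$f0), fs / 2), call. = FALSE)

  n_voiced <- round(dur * fs)
  t_voiced <- (seq_len(n_voiced) - 1) / fs
  f0_inst <- stats::approx(contour$times, contour$f0, xout = t_voiced,
                           rule = 2)$y
  phase <- 2 * pi * cumsum(f0_inst) / fs

  k <- seq_len(n_harmonics)
  a_k <- (1 / k^harmonic_decay)
  a_k <- amp * a_k / sum(a_k)            # peak of the harmonic sum <= amp
  voiced <- rep(0, n_voiced)
  for (i in k) voiced <- voiced + a_k[i] * sin(i * phase)

  # linear attack / release envelope
  env <- rep(1, n_voiced)
  if (env_attack > 0) {
    na <- min(n_voiced, round(env_attack * fs))
    env[seq_len(na)] <- seq_len(na) / na
  }
  if (env_release > 0) {
    nr <- min(n_voiced, round(env_release * fs))
    env[n_voiced - nr + seq_len(nr)] <- env[n_voiced - nr + seq_len(nr)] *
      rev(seq_len(nr) / nr)
  }
  voiced <- voiced * env

  n_lead <- round(lead_silence * fs)
  n_tail <- round(tail_silence * fs)
  x <- c(rep(0, n_lead), voiced, rep(0, n_tail))
  if (noise_rms > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    x <- x + stats::rnorm(length(x), 0, noise_rms)
  }

  gt <- list(onset = n_lead / fs, offset = n_lead / fs + dur,
             contour = contour, spec = contour$spec)
  structure(list(samples = x, fs = fs, subject_id = subject_id,
                 tone = tone, trial = trial, ground_truth = gt),
            class = "voice_recording")
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording> %.2f s @ %g Hz, subject %s tone %s trial %s\n",
              length(x$samples) / x$fs, x$fs, x$subject_id, x$tone, x$trial))
  invisible(x)
}
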