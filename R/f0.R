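#' Estimate the F0 track of a voice recording by harmonic-series scoring
#'
#' Short-time Fourier analysis between the detected voice bounds: every
#' `hop` seconds a Hann-windowed frame (centred on the analysis time) is
#' zero-padded and transformed; spectral peaks are collected and each peak in
#' the `[fmin, fmax]` search band is scored as a candidate fundamental by
#' summing the magnitudes at its first `n_harm` harmonic positions (with a
#' one-bin tolerance). The fundamental is the lowest-frequency candidate of
#' the dominant harmonic series, i.e. ties in series energy break toward the
#' lower frequency; the winning peak is refined past the FFT bin resolution
#' by parabolic interpolation. Frames whose dominant series carries
#' negligible energy relative to the spectral floor are marked unvoiced, and
#' a short median filter suppresses isolated octave errors.
#'
#' @param rec A `voice_recording`.
#' @param bounds A `voice_bounds`; defaults to bounds detected from the
#'   recording's default energy track.
#' @param window_length Analysis window length in seconds (default 0.04).
#' @param hop Frame step in seconds, the minimal time unit of the analysis
#'   (default 0.005).
#' @param fmin,fmax F0 search band in Hz (defaults 100 and 500, covering
#'   female speakers).
#' @param n_harm Harmonics summed in the series score (default 5).
#' @param zero_pad Zero-padding factor of the FFT (default 4; the FFT length
#'   is rounded up to a power of two).
#' @param voicing_ratio A frame is voiced when its best series energy
#'   exceeds `voicing_ratio` times the median spectral magnitude times the
#'   number of harmonics summed (default 5).
#' @param median_k Width of the octave-error median filter in frames
#'   (default 5); set to 1 to disable smoothing.
#' @return An `f0_contour` with `times` (absolute seconds), `f0`, `voiced`,
#'   `hop`, and attributes `bin_width` (Hz) and `bounds`.
#' @export
estimate_f0_track <- function(rec, bounds = NULL, window_length = 0.04,
                              hop = 0.005, fmin = 100, fmax = 500,
                              n_harm = 5, zero_pad = 4, voicing_ratio = 5,
                              median_k = 5) {
  stopifnot(inherits(rec, "voice_recording"))
  if (is.null(bounds))
    bounds <- detect_voice_bounds(compute_energy_track(rec))
  stopifnot(inherits(bounds, "voice_bounds"))
  fs <- rec$fs
  if (!(fmin < fmax && fmax < fs / 2))
    stop("need fmin < fmax < fs/2", call. = FALSE)
  if (bounds$offset - bounds$onset < window_length)
    stop("analysis window longer than the voiced span", call. = FALSE)

  L <- round(window_length * fs)
  nfft <- 2^ceiling(log2(zero_pad * L))
  binw <- fs / nfft
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann

  centers <- seq(bounds$onset + window_length / 2,
                 bounds$offset - window_length / 2, by = hop)
  n_fr <- length(centers)
  f0 <- rep(NA_real_, n_fr)
  voiced <- rep(FALSE, n_fr)
  half <- floor(nfft / 2)
  freqs <- (0:half) * binw
  kmax_bin <- half + 1L

  for (j in seq_len(n_fr)) {
    s0 <- round(centers[j] * fs - L / 2)
    idx <- (s0 + 1):(s0 + L)
    if (idx[1] < 1 || idx[L] > length(rec$samples)) next
    xw <- rec$samples[idx] * win
    mag <- Mod(stats::fft(c(xw, rep(0, nfft - L))))[1:kmax_bin]
    med_mag <- stats::median(mag)

    # local maxima of the magnitude spectrum
    pk <- which(diff(sign(diff(mag))) < 0) + 1L
    cand <- pk[freqs[pk] >= fmin & freqs[pk] <= fmax]
    if (!length(cand)) next

    # harmonic-series score for each candidate fundamental
    scores <- vapply(cand, function(b) {
      f <- freqs[b]
      k <- seq_len(n_harm)
      k <- k[k * f < fs / 2]
      s <- 0
      for (kk in k) {
        hb <- round(kk * (b - 1)) + 1L
        lo <- max(1L, hb - 1L); hi <- min(kmax_bin, hb + 1L)
        s <- s + max(mag[lo:hi])
      }
      s
    }, 0)

    # dominant series; ties (within half a percent) go to the lower frequency
    best <- max(scores)
    winner <- cand[which(scores >= best * (1 - 5e-3))[1]]
    n_used <- sum(seq_len(n_harm) * freqs[winner] < fs / 2)
    if (best < voicing_ratio * med_mag * max(n_used, 1)) next

    # parabolic refinement of the fundamental peak
    b <- winner
    if (b > 1 && b < kmax_bin) {
      a <- mag[b - 1]; bb <- mag[b]; g <- mag[b + 1]
      den <- a - 2 * bb + g
      delta <- if (den != 0) 0.5 * (a - g) / den else 0
      delta <- max(min(delta, 0.5), -0.5)
    } else delta <- 0
    fhat <- (b - 1 + delta) * binw
    if (fhat >= fmin && fhat <= fmax) {
      f0[j] <- fhat
      voiced[j] <- TRUE
    }
  }

  if (median_k > 1 && sum(voiced) >= median_k) {
    k <- if (median_k %% 2 == 0) median_k + 1 else median_k
    f0[voiced] <- stats::runmed(f0[voiced], k, endrule = "median")
  }

  structure(list(times = centers, f0 = f0, voiced = voiced, hop = hop,
                 spec = NULL, shape = NULL),
            class = "f0_contour",
            bin_width = binw, bounds = bounds)
}
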