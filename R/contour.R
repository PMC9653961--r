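#' Specify a Mandarin tone F0 contour
#'
#' A contour specification holds the anchor points of a single-syllable
#' lexical-tone F0 trajectory: onset and offset frequency, the dipping-tone
#' minimum (tone 3 only), and the phonation duration. Tone shapes follow the
#' canonical Mandarin inventory: tone 1 level, tone 2 high-rising, tone 3
#' falling then rising through a minimum, tone 4 sharply falling.
#'
#' @param tone Tone label, integer 1--4.
#' @param f0_onset F0 at voice onset, Hz.
#' @param f0_offset F0 at voice offset, Hz. Defaults to `f0_onset` for tone 1.
#' @param duration Phonation duration in seconds. Defaults to the per-tone
#'   durations used throughout the package (0.82, 0.84, 0.71, 0.45 s).
#' @param f0_min Minimum F0 of the dipping tone (tone 3 only), Hz.
#' @param min_position Position of the tone-3 minimum as a fraction of the
#'   duration, in (0, 1). Default 0.6.
#' @return An object of class `contour_spec`.
#' @examples
#' contour_spec(2, f0_onset = 204, f0_offset = 244)
#' @export
contour_spec <- function(tone, f0_onset, f0_offset = NULL, duration = NULL,
                         f0_min = NULL, min_position = 0.6) {
  if (!(length(tone) == 1L && tone %in% 1:4))
    stop("'tone' must be one of 1, 2, 3, 4", call. = FALSE)
  tone <- as.integer(tone)
  if (is.null(duration)) duration <- tone_default_durations()[tone]
  if (is.null(f0_offset)) {
    if (tone != 1L) stop("'f0_offset' is required for tones 2-4", call. = FALSE)
    f0_offset <- f0_onset
  }
  stopifnot(duration > 0, f0_onset > 0, f0_offset > 0)
  if (tone == 2L && f0_offset < f0_onset)
    stop("tone 2 requires f0_offset >= f0_onset (rising contour)", call. = FALSE)
  if (tone == 4L && f0_offset > f0_onset)
    stop("tone 4 requires f0_offset <= f0_onset (falling contour)", call. = FALSE)
  if (tone == 3L) {
    if (is.null(f0_min))
      stop("tone 3 requires 'f0_min'", call. = FALSE)
    if (f0_min > min(f0_onset, f0_offset))
      stop("tone 3 requires f0_min <= min(f0_onset, f0_offset)", call. = FALSE)
    if (!(min_position > 0 && min_position < 1))
      stop("'min_position' must lie strictly in (0, 1)", call. = FALSE)
  } else {
    f0_min <- NULL
  }
  structure(list(tone = tone, f0_onset = f0_onset, f0_offset = f0_offset,
                 f0_min = f0_min, min_position = if (tone == 3L) min_position else NULL,
                 duration = duration),
            class = "contour_spec")
}

#' Per-tone default phonation durations (seconds)
#'
#' Level, rising and dipping tones are long; the falling tone is short.
#' @return Numeric vector of length 4 (tones 1--4).
#' @export
tone_default_durations <- function() c(0.82, 0.84, 0.71, 0.45)

# interpolate one monotone segment between (0, a) and (1, b)
.segment <- function(u, a, b, shape) {
  if (shape == "cosine") a + (b - a) * (1 - cos(pi * u)) / 2 else a + (b - a) * u
}

#' Sample an F0 contour from a specification
#'
#' Evaluates the tone trajectory every `hop` seconds. Tones 1, 2 and 4
#' interpolate onset to offset (tone 1 is constant when onset equals offset);
#' tone 3 falls from onset to `f0_min` at `min_position * duration`, then
#' rises to offset. Segment interpolation is linear by default; cosine easing
#' gives smooth (zero-slope) turning points.
#'
#' @param spec A [contour_spec()].
#' @param hop Sampling step in seconds (default 0.005).
#' @param shape `"linear"` (default) or `"cosine"` easing per segment.
#' @return An object of class `f0_contour` with fields `times`, `f0`,
#'   `voiced`, `hop`, and the generating `spec` and `shape` as attributes.
#' @examples
#' ctr <- make_contour(contour_spec(4, 254, 186, duration = 0.45))
#' range(ctr$f0)
#' @export
make_contour <- function(spec, hop = 0.005, shape = c("linear", "cosine")) {
  stopifnot(inherits(spec, "contour_spec"))
  shape <- match.arg(shape)
  if (!(is.numeric(hop) && length(hop) == 1L && hop > 0))
    stop("'hop' must be a positive number", call. = FALSE)
  times <- seq(0, spec$duration, by = hop)
  f0 <- contour_value(spec, times, shape)
  structure(list(times = times, f0 = f0, voiced = rep(TRUE, length(times)),
                 hop = hop, spec = spec, shape = shape),
            class = "f0_contour")
}

#' Evaluate a contour specification at arbitrary times
#'
#' @param spec A [contour_spec()].
#' @param t Times in seconds within `[0, duration]`.
#' @param shape Interpolation shape, `"linear"` or `"cosine"`.
#' @return F0 in Hz at each time.
#' @export
contour_value <- function(spec, t, shape = "linear") {
  stopifnot(inherits(spec, "contour_spec"))
  u <- pmin(pmax(t / spec$duration, 0), 1)
  if (spec$tone == 3L) {
    p <- spec$min_position
    f0 <- ifelse(u <= p,
                 .segment(u / p, spec$f0_onset, spec$f0_min, shape),
                 .segment((u - p) / (1 - p), spec$f0_min, spec$f0_offset, shape))
  } else {
    f0 <- .segment(u, spec$f0_onset, spec$f0_offset, shape)
  }
  f0
}

#' @export
print.f0_contour <- function(x, ...) {
  cat(sprintf("<f0_contour> %d frames, hop %.4g s, F0 %.1f-%.1f Hz, %d voiced\n",
              length(x$times), x$hop, min(x$f0, na.rm = TRUE),
              max(x$f0, na.rm = TRUE), sum(x$voiced)))
  invisible(x)
}
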