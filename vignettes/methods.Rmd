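---
title: "Methods: tone-contour acoustics, EMG turns, and the statistics layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tone-contour acoustics, EMG turns, and the statistics layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonelemg)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the decisions taken where the
design was genuinely open.

## The acoustic model

A sustained Mandarin tone utterance is treated as a quasi-harmonic signal:
a fundamental F0(t) with harmonics at integer multiples, embedded in
silence and noise. The analysis chain is:

1. **Energy track.** Short-time RMS in 10 ms frames stepped every 5 ms.
   The 5 ms hop is the minimal time unit of the whole acoustic analysis;
   every subsequent quantity is defined on this grid.
2. **Voice bounds.** The baseline is the median RMS of the leading-silence
   frames (frames before the first frame above half the peak). Voice onset
   is the start of the first run that exceeds
   `baseline + threshold_frac * (peak - baseline)` and stays above it for
   at least `min_voiced` seconds; offset is the end of the last such run.
   Defaults `threshold_frac = 0.1` and `min_voiced = 50` ms make the rule
   robust to breathy onsets and to clicks. With the default linear 20 ms
   attack of the synthesizer, the detected onset lands within one hop of
   the true onset on clean signals and within two hops at 20 dB SNR (both
   are tested).
3. **F0 tracking.** Every 5 ms a 40 ms Hann-windowed frame centred on the
   analysis time is zero-padded 4x (FFT length rounded up to a power of
   two) and transformed. Spectral peaks in the 100–500 Hz search band are
   candidate fundamentals; each is scored by summing the spectral
   magnitudes at its first five harmonic positions with a one-bin
   tolerance, and the dominant series wins, ties breaking toward the lower
   frequency (the fundamental is the *lowest* frequency of the strongest
   harmonic series — this is what makes the tracker robust to a weak first
   harmonic). The winning peak is refined by parabolic interpolation, so
   accuracy is well below the FFT bin width (5.4 Hz at 44.1 kHz, 3.9 Hz at
   16 kHz). Frames whose best series energy is below `voicing_ratio` (5)
   times the median spectral magnitude are unvoiced. A 5-frame running
   median suppresses isolated octave errors; it can be disabled
   (`median_k = 1`).
4. **Feature extraction.** Onset/offset F0 are read at the first/last
   voiced frame (F0 is undefined on unvoiced frames, so the energy bounds
   themselves are not used as feature anchors). The tone-3 minimum is the
   earliest global minimum strictly inside the contour; a minimum at an
   endpoint is flagged rather than reported. The maximal 5 ms drop is the
   largest decrease between consecutive frames, floored at zero; it is
   computed for every tone but is a designed feature of the falling tone.
   Deltas, rates (`delta / segment duration`) and the duration satisfy
   their defining identities exactly, and the test suite asserts them on
   every output.

### Parameter choices

| parameter | default | why |
|---|---|---|
| hop | 5 ms | minimal time unit of the analysis |
| energy frame | 10 ms | sharp bounds; shorter than the F0 window |
| F0 window | 40 ms | resolves the female F0 range (>= 4 periods at 100 Hz) while keeping tone-4 dynamics visible |
| zero-padding | 4x | cheap interpolation before the parabolic refinement |
| F0 band | 100–500 Hz | female speakers; configurable |
| harmonics scored | 5 | enough to disambiguate octaves at these F0s |
| onset threshold | 0.1 of baseline-to-peak | robust to breathy onsets |

The window length, search band, threshold fraction and scoring depth are
engineering choices of this implementation (only the 5 ms hop and the
general harmonic-series rule are fixed by the method being implemented);
all are exposed in `run_config()` and echoed, with an md5 hash, into every
output file.

Because frames are centred and must fit inside the voiced span, the first
and last analyzable frames sit half a window from the bounds; a measured
onset-to-offset change therefore underestimates the specified change of a
linear contour by `slope * window_length`. For the steepest tone (tone 4,
~150 Hz/s) that is ~6 Hz, within the two-bin recovery tolerance the tests
enforce; for the other tones it is 2 Hz or less.

## The EMG turns model

A **turn** is a change of waveform polarity with an amplitude excursion of
at least 100 µV both before and after the change. The reference points for
"before" and "after" are deliberately *sequential*: excursions are measured
between consecutive qualifying turning points (the classical
turns-amplitude convention), with the signal's starting value as the
reference for the first turn and the final sample closing the last
reversal. This reading makes the rule noise-robust — a sub-threshold wiggle
neither counts as a turn nor interrupts a larger monotone excursion — which
is the stated purpose of the 100 µV threshold. The alternative strict
both-adjacent-flanks reading is noise-fragile (a 5 µV dip inside a 150 µV
rise would disqualify the surrounding turn) and is not used. Boundary
extrema require both flanks by default; `boundary = "relaxed"` accepts a
one-sided boundary extremum.

Implementation notes: candidate turning points are sign changes of the
first difference with plateaus collapsed to their first sample; the
qualification walk tracks running extremes on *both* sides until the first
confirmed reversal (before any reversal is confirmed the direction is
genuinely unknown), then alternates. The detector is verified, on
enumerated small extrema configurations and thousands of random signals,
against an independently coded per-sample brute-force implementation of the
same rule.

Epochs are 50 ms, non-overlapping, aligned to the start of the recording;
a trailing partial epoch is discarded. Turn frequency is count/epoch
duration; the peak turn frequency is the maximum across epochs. A
symmetric triangle wave of frequency f with 200 µV peak-to-peak yields
exactly 2f turns per second, the textbook check.

## The statistics layer

* **Cohen's d** uses the pooled SD and is reported as a magnitude (matching
  the convention of two-group clinical tables); the direction is kept as
  metadata. It is invariant under common affine transformations of both
  groups, which the tests assert.
* **Student's t** defaults to the pooled two-sided form. On the printed
  summaries of the reference tables, several p-values are only consistent
  with one-sided or unequal-variance variants, so `--welch` and one-sided
  alternatives are provided, and p-values are treated as diagnostics rather
  than reproduction targets; the effect sizes, which *are* exactly
  reproducible from the summary statistics, are the acceptance quantities.
* **Chi-squared** is Pearson's without continuity correction by default
  (Yates optional), with expected counts returned and a small-cell warning.
* **ICC** is the two-way absolute-agreement single-measure form ICC(A,1),
  computed from the subjects-by-trials mean squares; ICC(3,1) is available
  and the form is always recorded beside the estimate. The cross-trial SD
  is the mean over subjects of the within-subject SD. Duplicated trials
  give ICC exactly 1 and cross-trial SD exactly 0 (the exact limit is
  special-cased so floating-point cancellation cannot blur it); zero
  between-subject variance is flagged as degenerate rather than reported
  as a number. The implementation is validated against an independent
  reference implementation on a frozen fixture and by variance-component
  recovery in simulation.
* No multiple-testing correction is applied (by design, matching the
  reporting convention of the tables the report mirrors); the report
  settings say so explicitly. Missing data are handled by listwise
  deletion per feature, with counts logged.

## The synthetic-data generator

The generator exists so that every stage has inputs with exact ground
truth. It emulates:

* **Tone contours** as piecewise-linear (optionally cosine-eased)
  trajectories between the onset, offset and (tone 3) minimum anchors.
  Tone 1 interpolates onset to offset, so near-level utterances with a
  small nonzero drift can be simulated; tones 2/4 are monotone; tone 3
  falls to its minimum at 0.6 of the duration (the sketch-level position
  of the dip; configurable) and recovers.
* **Voice** as a sum of harmonics locked to the contour's running phase
  integral with 1/k amplitude decay, a linear attack/release envelope,
  lead/tail silence and optional Gaussian noise. Default durations per
  tone are 0.82, 0.84, 0.71 and 0.45 s — the falling tone is short — and
  the default sampling rates (44.1 kHz voice, 10 kHz EMG) are engineering
  choices.
* **EMG** as a piecewise-linear zig-zag through alternating extrema placed
  at the requested turns-per-second rate, amplitudes uniform in
  (120, 600) µV, plus *uniform* noise below +/-50 µV. Uniform (not
  Gaussian) noise is what makes the construction guarantee exact: its
  peak-to-peak excursion stays below the 100 µV threshold, so the
  generator's turn list is provably the rule's answer on the clean signal
  and remains recoverable from the noisy one.
* **Cohorts** by a two-level Gaussian model: one latent value per subject,
  tone and feature drawn from the group's (mean, SD), and trials drawn
  around it with the feature's cross-trial SD; lesion-side peak turn
  frequencies are drawn once per subject and tone. The default population
  parameters are the package's reference tables
  (`acoustic_reference()`, `turns_reference()`,
  `reliability_reference()`).

**Negative draws.** Frequency-valued quantities cannot physically be
negative, but the generator's purpose is to emulate *published group
moments*, and for the most dispersed cell (tone-1 peak turn frequency in
the CT+ group, mean 442.4, SD 285.0) about 6% of the Gaussian mass lies
below zero. Redrawing from the positive half would shift that group's mean
by roughly +36 Hz and shrink its SD by ~11%, moving the recovered effect
size from 1.19 to about 1.07 — i.e. truncation would make the generator
systematically *not* reproduce the statistics it is parameterized by. The
default is therefore to keep raw Gaussian draws (`negative = "allow"`);
`negative = "redraw"` is available and records its truncation count.

What the generator does **not** emulate: vocal-fold or motor-unit
biophysics (no jitter/shimmer, no formant structure, no motor-unit action
potential shapes), within-subject correlation *across* features (features
are drawn marginally), and non-Gaussian tails of real clinical
distributions. Passing recovery tests on these signals therefore
demonstrates correctness of the algorithms under the stated signal model,
not clinical performance on real voices.

## Numerical and degenerate-input choices

* FFT length is the next power of two above 4x the window; bin width is
  reported on every contour so tolerances can be stated in bins.
* Parabolic interpolation is clamped to half a bin; candidates whose
  refined frequency leaves the search band are dropped.
* Ties in harmonic-series score (within 0.5%) resolve to the lower
  fundamental; the tone-3 minimum resolves to the earliest frame.
* All-zero or all-silent input raises "no voice detected"; a window longer
  than the voiced span, a recording shorter than one frame/epoch, fewer
  than two voiced frames, and duplicate subject-tone EMG rows are errors,
  not NAs.
* Missing trials average over the available ones with a warning; a missing
  recording becomes a logged exclusion of that trial, not a failed run.

## Problem sizes used by the tests and the acceptance script

Chosen to give stable Monte-Carlo estimates at interactive runtimes: 1,000
random signals (plus exhaustive small-extrema enumerations) for the
turn-rule equivalence; four noiseless 44.1 kHz tones for F0 recovery;
10,000 null replicates for the t-test's type-I error (band 0.04–0.06);
1,000 replicates for ICC recovery of sigma_b^2/(sigma_b^2+sigma_w^2) = 0.9412
at 20 subjects x 3 trials (tolerance 0.015 = the estimator's known
finite-sample bias of ~0.006 at n = 20 plus three standard errors); and
2,000 replicate 17 + 71 cohorts for recovery of the tone-1 effect size
(tolerance three Monte-Carlo standard errors; note the sample d statistic
itself is biased upward by less than 1% at these group sizes). The
end-to-end demo runs 6 + 6 subjects at 16 kHz.

## Known limitations

* The F0 tracker assumes quasi-harmonic, monophonic voicing; it is not a
  general pitch tracker for running speech.
* Endpoint features inherit a half-window bias on steep contours (see
  above); contour-level comparisons on the normalized 0..1 grid do not.
* The two-level Gaussian cohort model implies single-trial ICCs somewhat
  below published trial-averaged reliabilities when both the group SD and
  the cross-trial SD are taken from the same tables; the generator is a
  statistical stand-in, not a fitted model of the cohort.
* Peak turn frequency of a constant-rate generator is quantized to
  1/epoch = 20 Hz steps, which adds a small positive bias relative to the
  nominal rate in end-to-end (file-level) simulations; the feature-level
  cohort simulator does not have this bias.
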