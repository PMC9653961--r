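# tonelemg

Quantitative analysis of Mandarin lexical-tone production and laryngeal
muscle activity, for voice clinicians and speech scientists studying
unilateral vocal fold paralysis (UVFP) with or without cricothyroid (CT)
muscle involvement.

Mandarin distinguishes words by four pitch patterns: tone 1 is level, tone 2
high-rising, tone 3 dips through a minimum, tone 4 falls sharply. Because
the CT muscle is the vocal-fold tension controller that raises pitch, CT
dysfunction should blunt exactly the rising and falling tones. Testing that
requires (a) an objective parameterization of the F0 contour of each
sustained tone utterance, (b) a quantitative index of laryngeal muscle
activation from EMG, and (c) the group statistics to compare patients with
and without CT involvement. This package implements all three, plus a
synthetic signal generator with exact ground truth so the whole pipeline is
verifiable end to end.

## What it computes

**Acoustic tone features.** From a mono WAV recording of one sustained tone:
the RMS energy track; voice onset (ON) and offset (OFF) by an
energy-threshold rule; the F0 contour between them by short-time Fourier
analysis at a 5 ms hop, where each frame's fundamental is the
lowest-frequency member of the dominant harmonic series (harmonic-series
scoring with parabolic peak interpolation); and the feature set

- F0 at ON and OFF; phonation duration ΔT;
- ΔF0(ON→OFF) and its rate ΔF0/ΔT (levelness of tone 1, rise of tone 2,
  fall of tone 4);
- for tone 3, the contour minimum MIN and the segments ΔF0(ON→MIN),
  ΔF0(MIN→OFF) with their rates;
- for tone 4, the maximal F0 drop per 5 ms frame step.

Three trials per tone are analyzed separately and averaged; trial-to-trial
reliability is quantified by the two-way intraclass correlation ICC(A,1)
and the cross-trial SD.

**EMG turns analysis.** A turn is a polarity change of the raw EMG waveform
with an amplitude excursion of at least 100 µV both before and after the
change (sequential Willison-style counting, so sub-threshold noise wiggles
neither create turns nor break larger excursions). The recording is binned
into non-overlapping 50 ms epochs; turn frequency is turns per epoch
divided by the epoch duration, and the **peak turn frequency** — the
highest epoch turn frequency during the phonation — indexes muscle
activation.

**Group statistics.** Two-group comparisons use Student's t (pooled,
two-sided by default; Welch and one-sided variants available), chi-squared
for nominal data, and the pooled-SD effect size

d = |m₂ − m₁| / s_p,  s_p = √(((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2)).

## Worked example

Effect size from published-style group summaries (CT+ n = 17 vs CT− n = 71,
tone-1 peak turn frequency 442.4 ± 285.0 vs 730.6 ± 231.6 Hz):

```r
library(tonelemg)
d <- cohens_d(442.4, 285.0, 17, 730.6, 231.6, 71)
round(c(d = d$d, s_pooled = d$s_pooled), 2)
#>        d s_pooled
#>     1.19   242.40
```

A pooled SD of 242.4 Hz and a standardized difference of 1.19 — a large
effect: the CT-involved group's muscle activation is more than one pooled
SD lower.

End-to-end on a self-contained synthetic cohort (6 + 6 subjects, three
voice trials per tone plus one EMG trace per tone, all generated with known
ground truth and analyzed from the files):

```r
res <- make_demo(seed = 1, fs_voice = 16000)
res$report$turns[, c("tone", "mean_ct_pos", "mean_ct_neg", "p", "cohens_d")]
#>   tone mean_ct_pos mean_ct_neg          p   cohens_d
#> 1    1    633.3333    630.0000 0.97604031 0.01777852
#> 2    2    470.0000    613.3333 0.27724051 0.66345702
#> 3    3    500.0000    750.0000 0.03431070 1.41398734
#> 4    4    506.6667    906.6667 0.01815163 1.62829597
```

Each row compares the lesion-side CT peak turn frequency between the groups
for one tone (at n = 6 per group the estimates are noisy; the simulated
population difference is recovered at full cohort size). The report object
also carries the 21-row acoustic feature comparison and the 16-row
test-retest reliability table:

```r
head(res$report$reliability[, c("tone", "feature", "cross_trial_sd", "icc")], 4)
#>   tone      feature cross_trial_sd       icc
#> 1    1        onset     9.26749875 0.9389884
#> 2    1       offset    10.88125747 0.9519910
#> 3    1 delta_on_off     7.54447849 0.9043845
#> 4    1     duration     0.06712616 0.8064171
```

`run_pipeline()` does the same on any cohort directory with a
`manifest.csv` and `<subject>_t<tone>_tr<trial>.wav` /
`<subject>_t<tone>.csv` files, writing a CSV/JSON report bundle stamped
with the configuration hash. A thin CLI with `synth`, `analyze` and `demo`
subcommands lives at `inst/scripts/tonelemg-cli.R`.

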