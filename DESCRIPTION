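Package: tonelemg
Title: Mandarin Tone F0 Contour and Laryngeal EMG Turns Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic acoustic analysis of the four Mandarin lexical tones
    (RMS energy tracking, voice onset/offset detection, short-time Fourier
    fundamental-frequency estimation via harmonic-series scoring, and a
    tone-contour feature set: onset/offset F0, rise/fall ranges and rates,
    dipping-tone minimum, maximal 5 ms F0 drop), quantitative turns analysis
    of laryngeal electromyography (sequential 100 microvolt turn counting,
    50 ms epochs, peak turn frequency), and the accompanying statistics
    layer (pooled-SD Cohen's d, Student's t, chi-squared, two-way
    intraclass correlation and cross-trial SD for test-retest reliability).
    Includes a synthetic voice and EMG generator with known ground truth so
    the whole pipeline is testable end to end, and a cohort-level report
    builder for two-group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
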