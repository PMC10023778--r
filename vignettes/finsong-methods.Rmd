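---
title: "Methods: synthetic fin whale song deployments and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic fin whale song deployments and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The monitoring problem

A single duty-cycled hydrophone (here: the first 30 minutes of every
hour, a 50% duty cycle) records for years at a high-latitude site. Fin
whale song dominates the low-frequency band in the singing season
(September–April): stereotyped 20 Hz downsweep notes (25 → 15 Hz over
0.5–1 s), an optional ~130 Hz upsweep component sharing the same timing,
and occasional backbeats (~0.8 s, 18–20 Hz). Notes come in sequences
with a regular inter-note interval (INI), separated by within-song
silences (rests, tens of seconds) and by between-song gaps (20 minutes
or more). The analysis products are weekly presence/detection rates,
their seasonal and interannual structure, their relation to sea-surface
temperature, and the INI pattern (unimodal singlet vs bimodal doublet)
per singing season.

## Synthetic deployments

`synth_deployment()` is first-class, tested code, not a fixture: it
defines the study conditions everything downstream is validated under.

* **Notes** are linear chirps under a Tukey window (`alpha = 0.25`). The
  field literature specifies band and duration but not a waveform; a
  linear sweep is the simplest shape reproducing the spectrogram ridge.
  Note level is expressed in dB above the ambient floor; the shipped
  default (30 dB) represents a clearly audible song ("high SNR"), and
  detector robustness is regression-tested down to 10 dB. The true
  received-level distribution at any real site is unknown, so synthetic
  SNR is an explicit free parameter.
* **INIs** are Gaussian, truncated at ±3 SD and at zero, because season
  catalogues report mean ± SD only (`svalbard_song_params()`). Doublet
  songs alternate short/long modes exactly before jitter.
* **Rests** replace one inter-note interval: the onset gap at a rest
  position equals the drawn rest duration, and the flanking interval is
  excluded from the ground-truth INI list. (The alternative — adding a
  rest *on top of* an interval — would make the measured gap the sum of
  two draws and the recovery targets for rest durations ill-posed.)
  Rest positions avoid the first/last interval and are never adjacent,
  so every sequence keeps at least two notes.
* **Paired 130 Hz notes** (`with_hf130`) sit exactly 1 s after each
  20 Hz onset, so both classes carry identical INI sequences, mirroring
  how the high-frequency component tracks the low one in real songs.
* **Noise** is Gaussian ambient (level in dB re full scale) plus
  broadband transient clicks band-limited to 10–100 Hz with exponential
  inter-arrival times — a deliberately adversarial stand-in for ice and
  vessel noise that *can* trigger false positives, so detector scoring
  is meaningful.
* **Duty cycling**: one WAV (PCM 16-bit mono, named by its ISO-8601
  start timestamp) per on-duty window; notes in off-duty minutes are
  dropped from audio but retained in the ground truth with an
  `in_audio = FALSE` flag, so conservation (truth = in-audio + off-duty)
  is checkable.
* **SST** is an annual sinusoid, baseline 3.2 °C, amplitude 1.7 °C,
  maximum in late July, plus daily Gaussian noise (SD 0.4 °C). These
  constants were chosen once so that monthly means sit inside the
  coastal envelopes the analysis assumes (roughly 1–4 °C October–May,
  4–8 °C June–September) with margin for the noise; optional cold
  anomalies (~0 °C weeks) and an ice-covered episode (below −2 °C) are
  available.

What the generator does **not** emulate: propagation loss, multipath,
source distance, non-Gaussian ambient spectra, triplet INI patterns, and
the real covariance between noise level and season. Passing tests
therefore demonstrate the *pipeline's* correctness under known ground
truth, not detector performance on any real deployment.

## The detector

The detector reproduces an energy-band configuration in common use for
20 Hz fin whale notes: downsample to 500 Hz (cascaded zero-phase
Chebyshev low-pass at 0.9 of each stage's Nyquist, integer factors of at
most 10 — zero-phase filtering keeps onsets unshifted), optional +14 dB
gain (score-invariant, kept for fidelity with field configurations),
spectrogram with 1024-sample Hamming frames, no zero padding, 1/8-frame
hop (0.488 Hz × 0.256 s resolution at 500 Hz).

Per frame, the score is

> equalized energy in the signal band (18–25 Hz) /
> equalized energy in the ratio band (25–100 Hz, signal band excluded),

where *equalized* means an exponential-moving-average background in log
energy (time constant 0.5 s, computed from previous frames only) is
subtracted. Design notes:

* The equalization algorithm behind the named tool in field software is
  not published; EMA background subtraction in log energy is the
  simplest causal estimator with the stated time constant. Whether the
  quoted "0.5 s" belongs to the ratio window or the equalization window
  is ambiguous in the source configuration; both are configurable here
  and 0.5 s is the equalization default.
* The construction is exactly scale invariant (a property test
  multiplies the waveform by a constant), and the ratio band suppresses
  broadband transients, which raise both bands equally.
* In white noise the *raw* in-band/ratio-band energy ratio equals the
  bandwidth ratio (7/75 at the default bands — a flat-PSD oracle in the
  tests); the *equalized* score fluctuates around 1 by construction.
* The score is smoothed by a 3-frame centered moving average.

Supra-threshold runs shorter than 0.1 s or longer than 2.5 s are
discarded, then runs separated by less than the 2.5 s neighbourhood are
merged ("minimum time between consecutive signals" read as a separation
constraint, so merging, not suppression). Because the maximum-duration
gate can drop over-extended runs at very low thresholds, the
"raising the threshold never increases detections" property is
guaranteed only from the calibrated threshold upward; the tests check it
on 6–60.

**Onset convention.** The reported onset is the end time of the first
analysis window whose raw in-band energy rises 6 dB above the
recording's median in-band level, scanning back at most one window from
the supra-threshold run. The first window containing *any* note energy
ends within one hop of the true onset, so this convention is SNR-robust
where the score-crossing time alone is not (the score needs overlap to
climb, which would bias onsets late at low SNR). On noise-free songs
detected onsets agree with ground truth within one hop (0.256 s) for
every season's INI model.

**Threshold.** Field configurations do not publish their score
threshold. The shipped default (6.0) was calibrated once against a
frozen seeded calibration scene and recorded in `detector_config()`:
pure-noise scores (10 × 100 s seeds) stay near 1 and never exceed ~2.2,
transient-rich noise stays below ~2, and clean notes exceed 20; 6 sits
well clear of both tails. It was not revisited afterwards.

**130 Hz band.** The same machinery with signal band 125–135 Hz is an
extension: field analyses ran the detector at 18–25 Hz and found the
130 Hz component on manual review. Detections carry the band's class
label; recordings where 130 Hz notes appear without any 20 Hz detection
are the "high-frequency component alone" case that qualifies for the
rates.

**Scoring.** Greedy one-to-one onset matching within 0.75 s (about half
the margin below the shortest plausible INI; configurable). True
negatives are counted over 1 s non-overlapping blocks of recorded time
without a ground-truth onset, because accuracy needs a negative universe
and none is inherent in a continuous recording.

## Rates

A recording belongs to the ISO-8601 week of its start timestamp (the
week convention is not dictated by anything upstream; ISO weeks are
deterministic and standard). PR counts a recording as positive if it has
at least one qualifying detection — a 20 Hz note, or a 130 Hz note in a
recording with no 20 Hz detection. Weeks with no recordings are emitted
with missing (not zero) rates; weeks with recordings but no detections
get zero. Partial recordings enter DR through their true recorded
minutes, so duty-cycle failures do not inflate the denominator. Weekly
SST is the mean/SD over the days available in that week, never
interpolated.

## Song structure

Segmentation splits a single-class note stream at gaps of ≥ 20 min (the
lower bound of between-song gaps; the 2 h upper bound is deliberately
not used as a merge rule — conservative separation). Within a song, a
gap is a rest when it exceeds 1.5 × the song's median INI; observed
rests (≈ 18–33 s) exceed observed INIs (9–15 s) by roughly that factor.
The median is computed over the song's sub-break gaps and refined once
after removing provisional rests — a batch estimate rather than a
running median, because a running median primed on a doublet song's
first gap (the short mode) would misclassify the long mode as a rest
before both modes entered the window. The regularity tolerance implied
by "a regular interval" is not quantified anywhere; the 1.5 factor is
this package's choice and is configurable.

Selection keeps songs with strictly more than 10 notes and at least 7
valid INIs, retains at most 20 INIs per song (the first 20
chronologically — the subsampling rule is unstated in field practice, so
the deterministic choice is logged for audit), and enforces 24 h
independence scanning chronologically with earliest-song-wins
tie-breaking. Rest-adjacent intervals are excluded before counting.
INIs are measured between detected onsets; how manual spectrogram
readings map to detector onsets is unknowable, but a constant onset bias
cancels in start-to-start differences.

Classification fits one- and two-component equal-variance Gaussian
mixtures (via mclust) and declares a song bimodal when the two-component
BIC wins by ≥ 2 — the conventional "positive evidence" margin — *and*
the modes are ≥ 2 s apart, which keeps jitter from being split into two
near-identical components. Degenerate inputs (zero variance) are
unimodal by definition without an EM fit. Doublet alternation is
reported separately from bimodality as the lag-1 sign-alternation rate
of INI differences, since a bimodal histogram does not by itself prove
alternating structure. Backbeats are carried as annotations but excluded
from INI analysis.

Rest statistics pool rest durations over songs grouped by modal INI
(median of the selected INIs) against a 12 s split — between the ~9 s
and ~15 s regimes the two rest populations attach to.

## Statistical layer

Both weekly rates are modelled as
`rate ~ s(month, bs = "cc", k = 12) + s(year, bs = "cr", k = #years)`
with a Gaussian family and identity link; month is the calendar month of
the ISO week's Thursday (the ISO pivot day), year the ISO year.
Smoothing parameters are selected by GCV; the basis dimensions and
selection method are this package's documented defaults, since none are
dictated upstream. The cyclic basis makes the fitted month curve
continuous in value and derivative across the December–January wrap (a
tested invariant, along with invariance to row order). A Gaussian
identity model on a rate bounded in [0, 1] is kept deliberately for
comparability; `PR` users can judge for themselves when a logit link
would serve better — it is out of the default path.

Spearman correlation (asymptotic, tie-tolerant) relates rates to weekly
SST with the conventional strength labels (weak < 0.39, strong > 0.60).
The October contrast is a two-sided Wilcoxon–Mann–Whitney comparison of
weekly DR, October versus the rest of the year, reported as a Z from the
tie- and continuity-corrected normal approximation; below 21 per group
without ties the p-value is exact. Season INI comparisons use
Kruskal–Wallis per note class with Holm-adjusted pairwise rank-sum
post-hocs (the post-hoc method is unstated in field practice; Holm
dominates Bonferroni at no cost). Calibration is tested by simulation:
type-I error of both rank procedures within [0.03, 0.07] at α = 0.05
over 1000 null replicates, and an injected October–November peak must be
localized by the month smooth.

## Problem sizes and runtime

The shipped validation uses desk-scale problem sizes chosen to make the
statistical tolerances meaningful: 20 songs × 21 notes per INI-recovery
pattern (≈ 400 selected INIs, so a ±0.3 s check sits at ≈ 2.6 standard
errors for the widest season SD), 30 songs × 2 rests per rest group
(n = 60), 200 seeded trials for classifier confusion, 1000 replicates
for test calibration. A full recovery run synthesizes ≈ 10 hours of
500 Hz audio and completes in about a minute per pattern on one CPU.

## Known limitations

* The detector is validated only against the generator's noise model;
  real ambient spectra are red, not white, and the calibrated threshold
  should be re-examined before use on field data.
* The segmentation's 1.5 × median rest threshold can clip extreme INI
  draws (beyond ~1.5 × the median) in very high-jitter unimodal songs,
  a small downward bias on recovered means that is visible in, and
  bounded by, the recovery tests.
* PR's Gaussian GAM can predict outside [0, 1] near the data edge.
* Songs spanning an off-duty gap are segmented from what the audio
  retains; no attempt is made to reconstruct notes the duty cycle
  discarded.
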