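---
title: "Methods: detection, scoring and inference in sleepmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, scoring and inference in sleepmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmem)
```

`sleepmem` implements the analysis chain of a within-subject, cross-over
pharmacology study of sleep-dependent emotional memory: polysomnography
preprocessing and sleep architecture, per-stage spectral band power, sleep
spindle and slow-oscillation detection with coupling density, recognition
memory scoring by signal-detection theory, and the repeated-measures
inferential layer. Because no individual-subject data of this kind are
publicly available, the package carries first-class synthetic generators
whose ground truth makes every downstream stage testable. This vignette
explains the models and the numerical choices.

## The synthetic night

`generate_eeg()` builds each channel as 1/f-amplitude-shaped Gaussian noise
(default spectral exponent 1, RMS 15 µV — the pink background typical of
resting EEG) and stamps events into the NREM stages of a configurable
stage sequence (default desk-scale night: 2 min Wake, 3 min S1, 12 min S2,
8 min S3, 5 min REM at 256 Hz; clinical-rate nights are configurable).

* **Spindles** are Gaussian-windowed sinusoids at `spindle_freq_hz`
  (default 13 Hz). `spindle_dur_s` is read as the ±2σ support of the
  envelope, so the default 1-s spindle has σ = 0.25 s — a realistic
  waxing-waning burst rather than a near-delta blip. Default peak
  amplitude 25 µV, density 2/min in each of S2 and S3.
* **Slow oscillations** are one-cycle asymmetric slow waves: a half-sine
  down state (default depth 100 µV, duration 0.6 s) followed by a half-sine
  up state whose duration is stretched so the waveform integrates to zero
  (up-state amplitude default 50 µV). Zero net area keeps the shape stable
  under later high-pass filtering. Amplitudes are configurable precisely so
  boundary tests can satisfy or violate each detector criterion on purpose.
* **Coupling**: a configurable fraction of spindles (default 0.5) is
  centred at a fixed lag after the trough of a same-channel slow
  oscillation (default +0.4 s, on the rising up state, where coupled
  spindles typically sit).

Counts are exact by construction — `round(density × stage minutes)` per
stage — and placement is uniform within stage blocks with a 2-s minimum
separation between same-type events, so detector recall metrics are not
confounded by merged events. Everything is bit-reproducible from the
config seed.

What the generator does **not** emulate: spatially correlated background
across channels, sleep-stage transitions inside an epoch, K-complexes,
artifacts other than amplitude excursions, and realistic EOG/EMG. Passing
detector tests on this synthetic night therefore demonstrates correctness
of the algorithms under known ground truth, not field performance on
clinical recordings.

## Preprocessing

Scalp channels are re-referenced to the contralateral mastoid (odd 10-20
indices to A2, even to A1). Midline channels — not used by any analysis
here — are referenced to the mastoid mean; this is documented for
completeness and affects no result. The analysis band-pass is a zero-phase
(two-pass) Butterworth 0.3–35 Hz, order 4 per pass: attenuation at
0.05 Hz and 45 Hz far exceeds 20 dB and the maximally flat response has no
passband ripple. Artifact rejection is an amplitude out-of-bounds test:
an epoch is discarded whole when any scalp sample of its 0.5-Hz
high-passed version exceeds ±200 µV. Whole-epoch granularity matches the
spectral pipeline, which consumes artifact-free 30-s epochs.

Sleep architecture uses 0-based, half-open 30-s epochs. Sleep onset (for
WASO) is the first non-Wake epoch after lights out; sleep latency is the
time from lights out to that epoch; sleep efficiency is total sleep time
as a percentage of time in bed. These definitions are asserted
algebraically on random hypnograms in the test suite.

## Spectral analysis

Power spectra use Welch's method: 4-s Hann windows at 50% overlap
(14 segments per 30-s epoch), scaled as one-sided density in µV²/Hz so
that band integrals recover variance (Parseval is tested against
closed-form tone and white-noise power). Per stage, PSDs are averaged
across artifact-free epochs first and integrated second.

Bands: SWA 0.3–1, delta 1–4, theta 4–7, slow sigma 9–11, fast sigma
12–15 Hz. Band integration is the trapezoidal rule on the linearly
interpolated PSD between exact band edges, which makes band powers exactly
additive; the 7–9 and 15–35 Hz gaps form an explicit complement band, so
relative powers (percent of total 0.3–35 Hz power) over the partition sum
to 100 to machine precision. The relative-power denominator — broadband
0.3–35 Hz rather than the sum of the five named bands — is a documented,
configurable choice: with it, typical NREM magnitudes come out near 60%
SWA and ~1% sigma, the scale on which such tables are usually reported.
Homologous-pair averages ("F" = mean of F3/F4, "C" = mean of C3/C4) are
computed on the PSDs, which is identical to averaging band powers.

## Spindle detection

The detector follows the wavelet-threshold family: a complex Morlet
wavelet centred at 12 Hz whose Gaussian time spread (σ_t = 0.06 s) gives a
half-power passband of ≈ 8.9–15.1 Hz — the sigma band. The detection
statistic is the squared wavelet magnitude smoothed by a 100-ms moving
average. The threshold is 4× the mean of this statistic, the mean taken
over all artifact-free S2+S3 samples of the same channel: a per-channel,
per-night baseline, which is the only reading of a "mean-referenced"
threshold that is stable over a whole recording.

Two numerical choices deserve note. First, thresholding **power** rather
than rectified amplitude: for narrowband Gaussian background the amplitude
trace has mean ≈ 1.25σ and a 4× mean threshold lands at ≈ 5σ — exactly
where a realistic spindle's response sits, making detection a coin flip —
whereas on the power trace, 4× the mean sits far above background yet far
below spindle peaks. This matches the detector lineage this method
follows; `threshold_stat = "amplitude"` remains available. Second, the
wide wavelet bandwidth shortens the envelope's correlation time, so
background excursions rarely persist past the 0.3-s minimum duration;
both choices together give recall and precision ≥ 0.95 at a burst
amplitude of 5× the background sigma RMS. Events are contiguous
supra-threshold excursions, bounded to 0.3–3.0 s (the duration floor
exists because single-sample crossings are otherwise counted), anchored at
the statistic's peak, and kept only when the peak's epoch is artifact-free
S2/S3.

## Slow-oscillation detection

The signal is band-passed 0.1–4 Hz (zero-phase Butterworth, order 2 per
pass) and scanned for consecutive zero-crossing triples
(positive-to-negative, negative-to-positive, positive-to-negative), with
sub-sample crossing times by linear interpolation — at these frequencies
events span thousands of samples and interpolation stabilises the duration
criteria. A triple is an event when the down state lasts 0.3–1.0 s, the
whole event is under 10 s, the trough reaches −80 µV or below, and the up
state stays under +140 µV.

On the filter band: the classical criteria above presuppose a low-pass
edge of a few hertz. A 0.4-Hz upper edge — occasionally quoted for this
detector family — is incompatible with its own duration criterion: a
0.1–0.4 Hz band-limited signal takes ≥ 1.25 s between zero crossings
except in low-amplitude ripples, and a numerical check shows a −100 µV,
0.6-s down state is attenuated to about −25 µV by such a band, so
essentially no event can pass the ≥ 80 µV criterion. The package therefore
defaults to 0.1–4 Hz, fully configurable. The detector's scan is tested
for exact equivalence against a brute-force enumeration of every
zero-crossing triple under the literal criteria, and the amplitude
boundary is exact: a trough of precisely −80 µV is retained, −79.9 µV is
rejected. Duration boundaries are probed 5 ms inside and 10 ms outside
the bounds because interpolated crossing times carry a ~2-ms
discretisation tolerance.

## Coupling

A spindle is coupled to a slow oscillation when its envelope peak lies
within ±1.25 s of the SO trough on the same channel. The spindle's single
representative time is its detection-statistic peak, the detector's most
robust landmark; the SO anchor is the trough. Pairing is exhaustive per
SO — a spindle inside two windows yields two coupled events, which the
density metric (coupled events per minute of stage, computed separately
for S2 and S3) counts as such. Time-reversal symmetry (offsets negate,
counts persist) is asserted in tests.

## Memory scoring

Confidence ratings 1–3 collapse to "present", 4–6 to "not present".
Buffer items (the 8 neutral pictures at encoding serial positions 1–4 and
45–48, which control primacy and recency) are excluded before any rate is
computed. Hit rate is P(present | old), false-alarm rate P(present | new),
accuracy the percent correct over the cell's 10 old + 10 new trials, and
d′ = z(hit) − z(false alarm) with the 1/(2N) rule for extreme rates (0 →
1/(2N), 1 → 1 − 1/(2N)); with 10 targets per cell, perfect rates are
common, so the correction is load-bearing, and it is configurable.
Difference scores are d′(test 2) − d′(test 1): negative means forgetting.
Outlier exclusion (±2.5 SD per dependent variable) is exposed as
`outlier_mask()` and applied at the group-analysis stage, not at scoring.

The behavioral generator draws old-item familiarity from N(d′, 1) and
novel items from N(0, 1) under the equal-variance model, with the 1–6
rating read off five fixed criteria symmetric around the decision
criterion (spacing `confidence_noise`, default 0.5); the middle criterion
is the decision criterion itself, so only the 3/4 boundary is
consequential after collapsing. The default criterion is 1.0, giving hit
and false-alarm rates near 0.84/0.16 at d′ = 2, the regime such studies
report. The default true-d′ table spans 1.84–2.43 with retention that
differs by condition and valence, emulating a cohort in which the drug
night protects memory that the placebo night lets decay. One caveat is
intrinsic and documented in tests: with 10-trial rates pushed through the
1/(2N) correction, the recovered d′ carries a binomial discretisation bias
that peaks around +0.12 near true d′ ≈ 1.5 under an unbiased criterion;
the test suite pins the pipeline's bias to the closed-form enumeration of
the corrected estimator rather than pretending the estimator is unbiased.

## Inference

All three within-subject factors are two-level, so every effect in the
2×2×2 repeated-measures ANOVA has one numerator degree of freedom, its F
is the squared one-sample t of the corresponding per-subject contrast
score, and sphericity is moot. With a between-subject covariate (body
weight, mean-centred — absorption scales with weight), contrast scores
are regressed on the covariate: the intercept test is the effect's F and
the slope test is the covariate × effect interaction, each on (1, n−2)
degrees of freedom — the classical RM-ANCOVA partition, verified in tests
to reproduce `aov()` Error-strata output exactly. A constant covariate
degrades gracefully to the covariate-free analysis. Incomplete subjects
are removed listwise and the per-analysis n is reported, since exclusions
differ per dependent variable.

Paired t-tests (two-sided; zero-variance differences flagged degenerate)
compare architecture and band-power variables between conditions, with
Holm-Bonferroni step-down control across each family. The correlation
screens are Pearson r per condition between sleep features and memory
variables, flagged against fixed Bonferroni-corrected alphas: 0.0025 for
the spectral screen and 0.004 for the event-density screen. Two-sided
p-values are used throughout, including for the directional sigma
hypothesis, which a user can halve explicitly if testing one-sided.

## Problem sizes and determinism

The shipped defaults are desk-scale: 30-minute nights at 256 Hz, six
EEG subjects per pipeline run, 28 behavioral subjects, and Monte-Carlo
suites of a few hundred replicates; all were chosen so a full run stays
interactive while keeping every statistical check well-powered. All
randomness flows from explicit config seeds; `run_pipeline()` reruns
byte-identically, and the manifest records seed and file checksums.

## Known limitations

* The EDF writer emits plain continuous EDF with one-second records and
  per-channel scaling; EDF+ annotations and discontinuous files are out of
  scope.
* The artifact test reproduces only the amplitude criterion; visual
  artifact and arousal rejection is inherently non-reproducible and is not
  modelled.
* The spindle detector reports envelope-peak amplitude in wavelet-response
  units (approximately the burst's carrier amplitude in µV), not
  peak-to-peak raw signal.
* Coupling is coincidence density only; phase-of-coupling (circular)
  statistics are not computed.
* The correlation screens treat features as independent draws per subject;
  no hierarchical pooling across channels or stages is attempted.
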