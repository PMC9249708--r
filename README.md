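# sleepmem

Sleep-EEG event detection and emotional-memory scoring for within-subject,
cross-over pharmacology designs.

Studies of sleep-dependent memory consolidation ask whether a night of
sleep — and drugs that reshape it — preferentially protects emotional
over neutral memories, and whether NREM physiology (sigma-band spindles,
< 1 Hz slow oscillations, their temporal coupling, slow-wave activity)
tracks that protection. `sleepmem` packages that full analysis chain for
R users: polysomnography input and preprocessing, per-stage spectra,
event detection, signal-detection memory scoring, and the
repeated-measures inferential layer — together with synthetic generators
that embed ground-truth events and known memory effects so every stage is
testable without human data.

## What it computes

* **Simulation** — `generate_eeg()` builds staged nights of 1/f background
  with injected spindles (Gaussian-windowed 9–15 Hz bursts) and slow
  oscillations (≥ 80 µV down states), returning exact ground truth;
  `generate_behavior()` simulates the two-condition × two-test ×
  two-valence recognition design (10 old + 10 new pictures per valence per
  test, 8 buffer items) under the equal-variance signal-detection model.
* **Sleep I/O** — plain-EDF read/write, hypnogram CSVs,
  contralateral-mastoid re-referencing, zero-phase 0.3–35 Hz band-pass,
  ±200 µV artifact-epoch rejection, and architecture metrics (TST, SL,
  WASO, SE, stage minutes).
* **Spectra** — Welch PSD (4-s Hann, 50% overlap) averaged over
  artifact-free epochs per stage; absolute and relative power for SWA
  (0.3–1 Hz), delta (1–4), theta (4–7), slow sigma (9–11) and fast sigma
  (12–15), with an explicit complement band so relative powers partition
  the 0.3–35 Hz range to exactly 100%.
* **Events** — Morlet-wavelet spindle detection (100-ms smoothed power
  vs 4× its NREM mean), zero-crossing slow-oscillation detection under
  the classical five criteria, ±1.25-s SO–spindle coupling, and
  per-stage event densities.
* **Memory** — confidence collapse (1–3 = present), hit/false-alarm
  rates, accuracy, d′ = z(hit) − z(FA) with 1/(2N) correction, test 2 −
  test 1 difference scores, ±2.5 SD outlier masks.
* **Inference** — 2×2×2 repeated-measures ANOVA with a mean-centred
  weight covariate (`rm_anova_2x2x2()`), paired t-tests, Holm-Bonferroni
  correction, and Bonferroni-screened Pearson correlations between sleep
  features and memory (`sleep_memory_screen()`).

`run_pipeline()` chains simulate → preprocess → detect → spectra → score
→ stats, writes every stage as CSV plus a JSON manifest with checksums,
and reruns byte-identically under a fixed seed.

## Worked example

```r
library(sleepmem)

sim <- generate_eeg(eeg_sim_config(seed = 1))
rec  <- bandpass_filter(rereference_contralateral_mastoid(sim$recording))
mask <- mark_artifact_epochs(rec, sim$hypnogram)

sp <- detect_spindles(rec, sim$hypnogram, mask)
so <- detect_slow_oscillations(rec, sim$hypnogram, mask)
cp <- couple_so_spindles(so, sp)
c(spindles = nrow(sp), slow_osc = nrow(so), coupled = nrow(cp))
#> spindles slow_osc  coupled
#>       40       59       21
event_density(sp, sim$hypnogram, "S2")
#> [1] 2
```

The default night injects 2 spindles and 3 slow oscillations per NREM
minute (20 NREM minutes), half the spindles coupled at +0.4 s after an SO
trough: the detectors recover 40/40 spindles, 59/60 slow oscillations and
21 coupled pairs, and the S2 spindle density of 2.0/min matches the
generating rate. On the behavioral side:

```r
beh    <- generate_behavior(behavior_sim_config(seed = 1))
scores <- score_sessions(beh$trials)
scores_w <- merge(scores, beh$subjects, by = "subject")
rm_anova_2x2x2(scores_w, covariate = "weight_kg")[c(1, 2, 4, 14), ]
#>      effect          F df_num df_den          p  n
#> 1 weight_kg  0.1466154      1     26 0.70490368 28
#> 2      drug  3.9453022      1     26 0.05763870 28
#> 4      test  7.3080601      1     26 0.01193709 28
#> 14 drug:test:emotion 1.5570084   1  26 0.22322543 28
```

Each row is one effect of the drug × test × emotion ANCOVA: F, its
degrees of freedom, p, and the number of complete subjects. A main effect
of test (p ≈ 0.012) reflects the simulated forgetting from the 12-h to
the 24-h test; whether the three-way interaction (drug-dependent
protection of negative memories) reaches significance at n = 28 varies
with the seed, as its simulated effect size is modest.

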