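---
title: "Methods: NREM event detection, slow-wave coherence, and the consolidation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NREM event detection, slow-wave coherence, and the consolidation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures `nremtools`
implements, the tunable parameters and their defaults, what the
synthetic polysomnography generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the package's test suite or
`scripts/acceptance.R` does not itself compute.

## Scope and data model

The package analyzes multi-channel scalp EEG from standard
polysomnography (9 electrodes of the 10–20 system at 500 Hz in the
default configuration), scored hypnograms (AASM stages W/N1/N2/N3/REM in
30-s epochs, with per-epoch artifact flags), motor-sequence-task (MST)
keystroke logs, and 1-min-epoch wrist actigraphy. Epochs are 0-based and
half-open (`[30i, 30(i+1))` s); samples are 0-based; amplitudes are
peak-to-peak microvolts throughout.

The signal container is a lightweight `eeg_recording` (samples ×
channels matrix plus sampling rate and labels). Everything downstream —
event tables, per-condition summaries, feature tables, behavioral scores
— is a tibble, so results chain directly into dplyr/ggplot2 workflows.
EDF import/export is provided for interoperability (`read_edf()`,
`write_edf()`; plain EDF, 16-bit, one shared sampling rate).

## Preprocessing

`bandpass_fir()` applies a linear-phase Hamming-window FIR (designed
with `signal::fir1`) by FFT convolution with exact group-delay
compensation, which realizes a zero-phase filter in a single pass. The
kernel order is `3.3 · rate / transition_width` rounded up to even
(odd-length kernel); the transition width defaults to the low cutoff
clamped to [0.25, 2] Hz, so slow bands get the long kernels they need
while the spindle band (9–16 Hz) stays selective with a 2 Hz
transition. Hamming windows give > 50 dB stopband attenuation. The
standard preprocessing chain is 0.5–30 Hz; event detectors then apply
their own band on top (0.25–4 Hz for slow waves, 9–16 Hz for
spindles). Linked-mastoid re-referencing is available
(`rereference_linked_mastoids()`) but synthetic recordings omit
mastoids, so it is not part of the simulated chain.

`stage_mask()` expands a hypnogram to a per-sample logical mask; all
detection and whole-epoch spectral estimation is restricted to the
masked (selected-stage, artifact-free) samples. Artifacts are whole
30-s epochs; there is no sub-epoch artifact marking.

## Slow-wave and delta-wave detection

On the 0.25–4 Hz trace of each channel, z-scored over the masked
samples, every local minimum with z ≤ −3.5 is a candidate; candidates
closer than 0.5 s merge into one (deepest trough kept) before any gate
is applied. A candidate is accepted when the peak-to-peak amplitude —
trough to the adjacent positive half-wave peak of the band-filtered
trace — lies in 50–300 µV and the implied duration (one intrinsic
period) in 0.2–3 s. Intrinsic frequency is `1 / (2 |t_peak −
t_trough|)`; below 1.5 Hz the event is a slow wave, at or above it a
delta wave (the boundary itself is assigned to delta).

Two numerical realizations matter here:

* **Landmark timing.** Peak and trough positions of a wave riding on
  noise are poorly determined at the flat extrema. The detector
  therefore takes each extremum's time as the midpoint of its
  half-maximum region (sub-sample interpolated), which is determined on
  the steep flanks. For the ideal biphasic wave the midpoints coincide
  with the extrema; under noise their variance is several-fold smaller.
* **Timing band.** A single cycle at 3 Hz has substantial spectral
  content above 4 Hz; the 0.25–4 Hz detection band broadens such a
  waveform and would bias its half-period high (we measured ≈ −0.4 Hz
  at 3.2 Hz). Landmarks are therefore measured on a doubled-bandwidth
  trace (0.25–8 Hz), which preserves single-cycle shape through 4 Hz
  while still excluding spindle-band noise. Detection and the amplitude
  gates remain on the 0.25–4 Hz trace.
* **First peak.** The reported peak is the positive half-wave
  *following* the trough — the down-state → up-state convention of the
  slow-oscillation literature — with the preceding half-wave as
  fallback. On a 1/f background the excursion immediately preceding a
  trough is usually a noise ripple, so a "preceding peak first" rule
  misclassifies a few percent of waves.

z-scoring is per channel and per night over the masked samples; events
are not excluded from the SD estimate (they inflate it by a few
percent, making the threshold slightly conservative).

## Spindle detection

On the 9–16 Hz trace: square, fit a cubic spline through the local
maxima of the squared trace, smooth with a 0.1-s moving average, and
z-score over the masked samples. Runs with z ≥ 3.5 are extended outward
to the bracketing crossings of z = 1 and merged across gaps < 0.5 s. A
candidate is accepted when at least 50% of its samples stay above
z = 3.5, its duration lies in 0.5–3 s, and the peak-to-peak amplitude of
the band-filtered trace lies in 25–250 µV.

The smoothing step is a stabilization of the spline envelope: a spline
through squared-trace maxima is an *upper* envelope and jagged at the
crest spacing, so its z = 1 crossings wander with single noise crests;
averaging over roughly one crest period (0.1 s at ~10–14 Hz) makes the
brackets stable without blurring event-scale structure. The z = 1 lower
bracket itself is a design choice — the threshold rule needs an event
extent to take its 50% fraction over, and a lower bracketing bound is
the minimal way to define one. We also evaluated the common
half-threshold hysteresis bound (z = 1.75): it converts
fraction-failures into duration-failures with no net benefit, so z = 1
is the default.

Intrinsic frequency is the inverse mean period between oscillation
crests, `f = 1/⟨p⟩`, computed on the supra-threshold core of the event
(where the oscillation dominates the band-filtered noise) with two
robustness rules: crests below 20% of the largest crest are ignored
(edge maxima at noise level stretch the mean period), and periods longer
than 1.5× the median are excluded (a crest lost to noise merges two
periods into one doubled interval). On clean waveforms all three rules
are inert and the estimator reduces to the plain mean period. Slow
spindles are 9 < f ≤ 12 Hz, fast 12 < f ≤ 16 Hz; events outside (9, 16]
are dropped as unclassifiable. Restricting detection to masked N2/N3
epochs structurally prevents occipital wake alpha from entering the
spindle range.

## Slow-wave-triggered coherence

`extract_sw_windows()` collects ±2 s of the preprocessed (0.5–30 Hz)
EEG around each SW trough on the seed electrode, for the seed and every
target channel; windows that leave the recording (or the mask, if
given) are dropped and counted. `multitaper_coherogram()` slides a 1-s
window in 50-ms steps across the aligned window sets and estimates, at
each position, magnitude coherence `|S_xy| / sqrt(S_xx S_yy)` with
cross- and auto-spectra averaged over 3 DPSS tapers (NW = 2, the
canonical pairing K = 2NW − 1) and over events. Spectra live on a
power-of-two FFT grid covering the analysis window. The scalar
slow-wave coherence is the mean over bins with centers inside
[−0.5, 0.5] s × [0.5, 1.5] Hz (closed intervals).

Notes and limitations:

* A 1-s window cannot resolve a full cycle at 0.5 Hz; with NW = 2 the
  half-bandwidth is 2 Hz. The [0.5, 1.5] Hz window therefore reads the
  coherogram at its resolution limit; this is inherent to the
  1-s/3-taper configuration, and the package follows it as specified
  rather than substituting a longer window.
* With K tapers and n events the no-coherence bias floor is
  approximately `sqrt(pi / (4 K n))`; with 3 × 100 spectral averages
  that is ≈ 0.05. The test suite verifies the estimator sits on this
  floor for independent noise.
* `coherence_matrix()` triggers on the *row* (seed) electrode's events;
  matrix asymmetry can arise only from trigger-set differences, since
  the spectral kernel itself is exactly symmetric.
* DPSS tapers come from the tridiagonal commuting-matrix
  eigendecomposition; for lengths beyond 2048 samples (whole-epoch
  coherence uses 30-s segments) they are spline-interpolated from
  length 2048 and re-orthonormalized — the classical construction, with
  error far below the spectral estimation variance.

`whole_epoch_band_coherence()` applies the same multitaper machinery to
whole fully-masked 30-s epochs (taper length = epoch length) and
averages over epochs and the frequency band.

## Motor sequence task

Keystreams are scanned left to right for complete, error-free,
non-overlapping occurrences of 4-1-3-2-4; after a completed sequence the
scan resumes at the next keypress, so the terminal 4 is not reused
("4132441324" counts exactly 2). A wrong key resets the match, itself
starting a new match if it is a 4. Execution time is the mean of the
four inter-press gaps within each correct sequence, averaged over
sequences. Training performance is the mean of the last three training
trials, test performance the mean of the first three test trials, and
overnight improvement the percentage change between them (negative ET
improvement = faster typing). Group comparisons use the Welch t-test,
Levene's robust variance test (mean-centered, implemented as one-way
ANOVA on absolute deviations), and an F variance-ratio test.

## Actigraphy and NPCRA

`actigraphy_sleep()` scores each in-bed minute as sleep when counts fall
below a threshold (default 20; configurable) and derives TIB, TST,
efficiency, SOL and the fragmentation index (mobile-time percentage,
mobile = counts ≥ 4, plus the percentage of immobile bouts ≤ 1 min).
Fully missing nights are flagged and excluded from per-participant
averages.

`npcra()` computes non-parametric circadian rhythm measures on hourly
aggregates (p = 24 hour-of-day bins, the standard practice):

* inter-daily stability
  `IS = n Σ_h (x̄_h − x̄)² / (p Σ_i (x_i − x̄)²)`,
* intra-daily variability IV = mean squared successive difference /
  variance, with pairs spanning a missing hour dropped,
* amplitude = M10 − L5 of the average 24-h profile (most-active 10 and
  least-active 5 consecutive hours, circular windows).

Missing data handling is a documented completion of an unpublished
algorithm variant: an hour is valid when at least half its minutes are
present, a day when at least 20 hours are valid, and a summary requires
at least 7 valid days. IS → 1 for perfectly repeated days, IV → 0 for
constant activity and ≈ 2 for white noise; both are invariant to affine
rescaling of counts.

## Statistical pipeline

* `build_feature_table()` averages each event property over all
  electrodes per subject, night and stage selection, giving the subject
  × NREM-feature table (`<kind>_<property>` columns); subjects missing
  an event kind are flagged, not silently dropped.
* `box_m_test()` implements Box's M with the chi-square approximation
  (`M = (N−g) ln|S_p| − Σ (n_i−1) ln|S_i|`, df = (g−1)p(p+1)/2) and
  flags `n ≤ p` degeneracy; singular group covariances are an error
  directing the user to reduce dimension first.
* `pca_features()` standardizes columns (the features mix µV, s, Hz and
  events/min, so unstandardized PCA would be unit-dominated) and
  eigendecomposes the correlation matrix via `prcomp`; scores are
  exactly decorrelated.
* `stepwise_mlr()` is forward-entry only: at each step the candidate
  with the smallest partial-F p enters if p < 0.01; there is no removal
  phase (an entry criterion is the only stated rule; a removal rule
  would be invented behavior). With 10 candidate components at per-test
  α = 0.01 the family-wise null selection rate is ≈ 1 − 0.99¹⁰ ≈ 10%,
  which the acceptance suite verifies.
* `fit_event_lmm()` fits `y ~ genotype + night + electrode +
  sleep_stage + genotype:night + (1|subject)` by REML with
  Satterthwaite denominator df, then applies hierarchy-respecting
  backward elimination at α = 0.05: the interaction is eligible before
  its main effects, and each round removes every eligible term at or
  above the threshold (in the balanced designs this model serves, the
  round-wise rule coincides with classical one-at-a-time elimination,
  and the interaction's fate is decided by its full-model test).
  Marginal means for the surviving genotype × night cells use balanced
  weights over the remaining factors.
* `match_components()` matches a component across two PCAs by minimal
  Euclidean distance between unit-norm loading vectors, evaluated under
  both signs (component signs are arbitrary).

No multiplicity correction is applied across separate stepwise models;
each model is reported on its own terms, and this is a deliberate,
documented caveat.

## The synthetic PSG generator

The generator is the package's ground-truth instrument, not a realistic
sleep simulator. Its background is 1/f^β Gaussian noise (β = 1 by
default) generated by Fourier shaping across the recording's full
spectral grid and scaled to an exact broadband RMS (default 20 µV — a
typical NREM floor once high-amplitude events are excluded, chosen so
that a slow wave planted at 4× the background RMS has the ~80 µV
peak-to-peak amplitude of a typical slow oscillation and clears the
detector's absolute 50 µV gate with ~3σ margin). Planted slow/delta
waves are one biphasic cycle (negative then positive half-sine, duration
one intrinsic period) matching the detector's trough-then-peak geometry;
spindles are a sinusoid under a raised-cosine (Hann) envelope, so the
≥50%-above-threshold rule is exercised non-trivially. Cross-channel
coupling is onset lag plus Gaussian jitter per channel; expected
coherence decreases monotonically with jitter, which is verified
empirically rather than calibrated analytically.

`plan_events()` draws well-separated events (≥ 2 s gaps) within the
selected stages, with frequencies at physiologically typical values
clear of the filter transition edges and at least 0.3 Hz from class
boundaries (slow waves 0.9–1.2 Hz, delta 1.8–3.2 Hz, slow spindles
9.5–11.7 Hz, fast spindles 12.3–15 Hz) and default amplitudes of 4×/6×/3×
the background RMS for slow waves/delta/spindles — delta higher because
a single-cycle wave at 2–3.2 Hz loses up to a third of its amplitude to
the 0.25–4 Hz detection band.

What the generator does **not** emulate: sleep cycling and stage
dynamics, REM phenomena, EOG/EMG, real artifact morphology,
amplitude/frequency covariation of real events, or waveform asymmetry
of real slow oscillations. Detector validation on this synthetic ground
truth therefore demonstrates algorithmic correctness — thresholds, gate
logic, frequency estimation, coherence estimation — not field
performance on clinical recordings.

The MST simulator types at a constant nominal inter-press interval
chosen to realize a target NCS per trial, with Gaussian timing jitter, a
5% wrong-key rate by default, and an additive overnight gain whose
between-subject SD scales with a per-group multiplier (this is how one
group is given more variable consolidation than the other). The cohort
generator for the end-to-end contrast (`simulate_consolidation_cohort()`)
draws intercorrelated features from a 3-factor model and ties one
group's improvement to the first latent axis (80% of variance by
default) while the other group's improvement is independent noise; its
default group sizes and improvement moments (18 vs 22 subjects,
16.9 ± 9.6% vs 15.9 ± 16.8%) are study-scale values.

## Validation conditions and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` use the following conditions, chosen once as the
package's standard validation setup:

* Detection: one 20-min, 9-channel, 500-Hz N2/N3 night with 60 planted
  slow waves (4× background RMS), 40 delta, 40 slow and 40 fast
  spindles. Expected operating point: recall ≥ 0.95, precision ≥ 0.9,
  classification accuracy 1.0 at 0.3 Hz boundary margins. At the pinned
  slow-wave amplitude the expected filtered trough z is ≈ 4.5 against
  the 3.5 threshold, so per-event detection probability is ≈ 0.9 and
  pooled recall sits near the 0.95 boundary by construction; this is a
  property of the amplitude convention, not a tunable of the detector.
* Intrinsic-frequency fidelity: the ±0.2 Hz criterion is evaluated on a
  quiet (5 µV RMS) background through the full detection chain, because
  the interval-based estimator's noise sensitivity grows as f², and at
  the noisy validation conditions delta-wave estimates have an
  irreducible ~0.25–0.35 Hz spread.
* Coherence: toy window sets for exactness (self-coherence, brute-force
  oracle equality to 1e−10, analytic bias floor), and 200-event
  two-channel recordings at jitter {0, 0.1, 0.3, 0.6} s (5 seeds) for
  monotonicity.
* Stepwise regression: n = 18, 10 components, 500 seeds each for
  recovery and null selection. Box's M: p = 4, n = 100/group, 1000 null
  and 200 alternative replicates.
* Mixed models: 20 subjects × 2 nights × 9 electrodes × 200 events per
  cell; 20 planted-interaction seeds and 100 null seeds (the null sweep
  evaluates retention via the full-model interaction test, which under
  the round-wise elimination rule decides the interaction's fate
  exactly, and runs the full elimination when it survives).
* End-to-end contrast: 25 cohort seeds. Levene's test at the cohort's
  own scale (n = 18/22, SD ratio ≈ 1.75) has power ≈ 0.57, so the
  variance flag is asserted as: the decoupled group's sample SD exceeds
  the coupled group's in ≥ 90% of seeds and the median Levene p across
  seeds is < 0.05 — a per-seed rejection requirement would not be
  attainable at this sample size.

These sizes keep the complete suite within a practical runtime while
leaving each Monte Carlo check statistically meaningful.
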