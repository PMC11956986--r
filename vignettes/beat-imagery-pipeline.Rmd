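---
title: "Frequency-tagged SSEPs of imagined musical beat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged SSEPs of imagined musical beat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When a listener imagines a binary (march-like) or ternary (waltz-like)
accent pattern on a metronomic 2.4 Hz auditory stimulus, does the EEG carry
a measurable steady-state evoked potential (SSEP) at the *imagined* beat
frequency — 1.2 Hz for binary, 0.8 Hz for ternary imagery — over and above
the stimulus-driven response at 2.4 Hz? Because the stimulus is physically
identical across imagery conditions, any condition difference at the
imagery frequencies indexes endogenous, perception-related processing
rather than acoustics. `beatssep` implements the complete multi-lab
analysis chain for this question: stimulus synthesis, SSEP extraction,
per-lab statistics, cross-lab meta-analysis, and a trial-level
brain–behavior regression, together with a synthetic multi-lab generator so
every stage is testable without any recordings.

## The stimulus

The stimulus is a 333.3 Hz pure tone, amplitude-modulated at 2.4 Hz with an
asymmetric Hanning envelope — a half-raised-cosine rise over 22 ms followed
by a half-raised-cosine fall over 394 ms, modulation depth 0 to 1 — and
then modulated again by an 11 Hz sinusoid that adds a pseudo-periodic
roughness. Design choices where the published description is silent:

* The 22 + 394 = 416 ms envelope cycle is zero-padded to the full 2.4 Hz
  period (416.67 ms) so the amplitude-modulation rate is exactly 2.4 Hz.
* The 11 Hz modulator is implemented as `(1 + m sin(2π·11 t)) / (1 + m)`
  with depth `m = 0.5` by default and configurable, since only the
  modulator's existence and rate are documented.
* The 3 s appended extension copies the *start* of the modulated waveform
  by default (`extension_source = "start"`), the choice being undocumented.
* The 880 Hz, 40 ms probe is mixed at gain 0.5 with 5 ms raised-cosine
  ramps to avoid broadband clicks; the mixed waveform is rescaled only if a
  sample would exceed full scale. The ternary probe onset defaults to
  33.732 s (the body text value; a figure caption reads 33.772 s — both are
  accepted via `probe_onset_ternary_s`).
* Audio is written as 32-bit float RIFF/WAVE at 44.1 kHz.

## SSEP extraction

The frequency-tagging chain is, in order: re-reference to the channel
average; zero-phase (forward–backward) Butterworth high-pass at 0.1 Hz,
order 4 (the order being an implementation choice — none is published);
epoch extraction from 1 s to 33 s after stimulus onset; element-wise trial
averaging; a plain DFT amplitude spectrum `2|X_k|/N` with no window or
zero-padding, so the resolution is exactly 1/32 Hz = 0.03125 Hz (the
published "0.03 Hz" is treated as rounded, not as a zero-padding mandate);
neighbor-bin noise subtraction; and a 3-bin average centered on the bin
nearest each target frequency, averaged (signed) across channels.

Numerical notes:

* **Filtering before epoching.** The high-pass runs on each full trial
  record before the 1–33 s epoch is cut, and the signal is demeaned and
  padded by odd reflection first: at a 0.1 Hz cutoff the filter poles have
  multi-second time constants, and without padding the start-up transient
  would leak into the epoch. Passband distortion at 2.4 Hz is below 1%.
* **Neighbor bins.** The correction subtracts the mean amplitude at bin
  offsets {−4, −3, +3, +4}: at Δf = 1/32 Hz these are the only offsets
  whose centers fall in the stated 0.09–0.15 Hz exclusion window on each
  side, and exactly two bins per side. Corrected amplitudes may be
  negative; channel averaging is signed, consistent with negative cell
  means in the published lab table.
* **Nearest-bin convention.** `k = round(f0/Δf)`: 0.8 → bin 26
  (0.8125 Hz), 1.2 → 38 (1.1875 Hz), 1.6 → 51 (1.59375 Hz), 2.4 → 77
  (2.40625 Hz).
* **Leakage is part of the measurement.** The target frequencies are not
  integer multiples of 1/32 Hz, so a rectangular-window DFT spreads each
  line across bins (Dirichlet kernel). The 3-bin noise-subtracted estimate
  of an off-bin sinusoid of amplitude A is a deterministic fraction of A
  (about 0.40·A at 1.2 Hz, 0.27·A at 0.8 Hz, 0.38·A at 2.4 Hz). The test
  suite checks the pipeline against an independent closed-form
  Dirichlet-kernel oracle to 1e−9 rather than against A itself.
* ICA-based artifact removal is out of scope (it requires manual component
  selection); the pipeline's entry point accepts pre-cleaned epochs.

## The synthetic multi-lab generator

`sim_config()` fixes the study conditions: 13 labs × 12 subjects, 10
imagery and 12 control trials, 64 channels at 1000 Hz, 36 s trials. The
population amplitude structure is anchored to the published descriptives: a
stimulus-frequency amplitude of 0.07 μV, near-zero baselines at the imagery
frequencies, an imagery-congruent increment of 0.03 μV, between-subject SD
0.02 μV, and a within-subject measurement SD of 0.05 μV for the
amplitude-level simulator (the scale of the published cell SDs).

Modeling decisions worth knowing:

* **Shared baseline, additive increment.** Each subject draws one
  truncated-at-zero normal baseline per frequency, shared across
  conditions, and the imagery-congruent increment is added
  deterministically. Drawing every condition cell independently from a
  truncated normal would bias the within-subject contrast below the
  injected increment whenever a cell mean sits near zero; the shared
  baseline keeps the contrast unbiased by construction and adds realistic
  within-subject correlation.
* **Zero-mean topography.** The sinusoidal signal is projected to channels
  with an alternating +1/−1 gain map. Average-referenced EEG has zero-sum
  topographies by construction, so this makes the average-reference step
  exact; a spatially uniform gain would be annihilated by it.
* **Phase-locked SSEPs.** Phases are drawn once per subject and held
  constant across trials, the steady-state assumption that justifies trial
  averaging; the suite checks that randomizing phase per trial destroys
  the averaged amplitude.
* **Noise.** Per channel and trial, 1/f^α noise (α = 1, spectrally shaped
  white noise, flat below 0.1 Hz) plus white noise. When the workflow is
  run scaled down (fewer trials, channels and samples), the noise SDs are
  scaled down too, preserving the per-bin spectral SNR of the full design:
  the amplitude spectrum is a modulus and therefore a *biased* detector
  when the per-bin noise amplitude rivals the sub-microvolt signal — a
  property of frequency tagging itself, not of the simulation.
* **Behavior.** Probe accuracy is Bernoulli through a logistic model on
  the subject's amplitudes and probe type; a response is correct when a
  binary probe is called "ON beat" under binary imagery only, and a
  ternary probe under ternary imagery only. Ratings (1–7) come from an
  ordered-logit cutpoint model on the same linear predictor.
* What the generator does **not** emulate: head-model topographies, ERP
  transients, artifacts (blinks, EMG), non-stationary noise. Passing tests
  therefore demonstrate correctness of the analysis chain on data obeying
  its assumptions, not robustness to real-world artifacts.

## Per-lab statistics and the power analysis

`rm_anova_oneway()` is the classical within-subject decomposition with the
Greenhouse–Geisser ε computed from the double-centered condition covariance
and applied unconditionally (no sphericity pre-test); effect size is
partial η². Post-hoc paired t-tests use Bonferroni with m = 3 (the three
condition pairs within a frequency, matching the many adjusted p = 1.00
entries in the published post-hoc table), capped at 1. Correlations use
pairwise deletion and report undefined cells (constant variables) as
absent.

The a priori power routine uses the noncentral-F "within factors"
convention: λ = f²·N·m·ε/(1−ρ), df₁ = (m−1)ε, df₂ = (N−k)(m−1)ε, with
k = 3 conditions as the groups, m = 10 repeated measures, ρ = 0.5, ε = 1,
α = .05, and f² = η² = .06 under the direct conversion f = √η² (the
`f2_method = "partial"` alternative f² = η²/(1−η²) is exposed). Under this
parameterization the smallest sample with power ≥ .80 is n = 15 (power
.794 at 14, .830 at 15), and `rm_power_mc()` — a split-plot Monte-Carlo
simulation of exactly the design the formula models — reproduces the
analytic power to within Monte-Carlo error. This combination of
conventions is the one we could verify against both the published minimum
sample size and the simulation; it is recorded here because power software
conventions for repeated measures differ and the mapping of
"conditions/repetitions" onto "groups/measurements" is otherwise
ambiguous.

## Meta-analysis

Each lab contributes four paired contrasts of channel-averaged SSEP
amplitude: binary−control and binary−ternary at 1.2 Hz, ternary−control
and ternary−binary at 0.8 Hz. For means, the SE is `sd(diff)/√n` — correct
for a within-subject contrast; note that printed per-condition means and
SDs alone cannot yield it, which is why the packaged summary-table fixture
supports only point differences and their cross-lab ranges, not pooled
estimates. Pooling is inverse-variance random effects with τ² by REML
(Fisher scoring; DerSimonian–Laird available), Cochran's Q with
fixed-effect weights, I² = max(0, (Q−df)/Q)·100, H² = Q/df, and Wald z
confidence intervals without the Knapp–Hartung adjustment (the published
symmetric CIs and z-style p-values indicate Wald). Moderator models
(mean music or dance years per lab) re-estimate τ² under the moderator
design and report the predicted effect at the moderator mean and mean ± 1
SD — the three-diamond forest convention; the published figures do not
state their moderator levels, so this is an implementation choice.

Median-difference meta-analysis pools per-lab medians of within-subject
differences with the normal-theory quantile SE,
`1.2533·(IQR/1.349)/√n`; a seeded bootstrap SE is available. The exact
method variant behind the published median analysis is unnamed, so the
suite checks the property that matters: for symmetric subject-level
differences the median pooling converges to the mean pooling.

## Trial-level regression

Probe accuracy is regressed on lab, music and dance years, imagery type,
probe type (ON/OFF the imagined beat), amplitude at the imagined-beat
frequency, and amplitude at the stimulus frequency, by an explicit IRLS
logistic fit with per-term Wald χ² (1 df). The published predictor list
includes both participant and lab identifiers, which are collinear as
dummies; the default therefore enters subjects through cluster-robust
(sandwich) standard errors rather than fixed effects (`subject_encoding =
"cluster"`), and the `"dummy"` mode raises an explicit aliasing error
naming the columns. Per-trial amplitudes are not always available (the
original analysis does not state whether single-trial spectra were used);
both granularities are supported, with subject-level amplitudes broadcast
across trials as the fallback. Separation is reported as non-convergence,
never as silent output.

## Problem sizes

The packaged tests and the acceptance script are sized for a single CPU:
spectral tests run at 200 Hz sampling with 2–16 channels and full 32-s
epochs (the frequency resolution, bin indices and leakage pattern are
identical to the 1000 Hz case); the Monte-Carlo power check uses 10⁴
replicates; effect-recovery uses 300 replicates of the 13 × 12 design at
the amplitude level; the logistic recovery uses 200 replicates of 10⁴
trials. The demonstration workflow under `analysis/` simulates 4 labs × 8
subjects × 8 channels with noise scaled to preserve the full design's
per-bin SNR.

## Known limitations

* Published pooled estimates, heterogeneity statistics, grand-average
  ANOVAs/t-tests, correlation tables and the trial-level Wald χ² cannot be
  reproduced from printed summaries alone — they require the raw
  per-subject recordings and a manual ICA step; the suite instead verifies
  the machinery by parameter recovery and closed-form oracles.
* One published cross-lab range bound (ternary−control, .149) is not
  derivable from the printed per-lab means (maximum difference .099); it
  is treated as a transcription inconsistency and not asserted.
* The quantile-based median SE assumes approximate normality of the
  within-subject differences; for heavy-tailed data prefer the bootstrap
  option.
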