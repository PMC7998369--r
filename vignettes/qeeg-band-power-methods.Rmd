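---
title: "Methods: mobile QEEG band power, BIC Bayes factors and effect sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobile QEEG band power, BIC Bayes factors and effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qeegpower` implements the statistical core of a mobile-EEG external-validity
experiment: does the spectral-power signature of default (resting) and
complex (mental arithmetic) neurocognitive states, long established in
laboratory QEEG, survive recording in an uncontrolled outdoor environment?
This vignette documents the model assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The analysis chain

A session is a continuous multichannel recording (µV) at 256 Hz from a
16-site extended 10–20 montage plus mastoids (M1/M2) and one infra-orbital
EOG channel (LVEOG), referenced at the vertex (CZ). The chain is:

1. **Epoching.** 1-second epochs with 50% overlap, each baseline-corrected
   by subtracting its per-channel mean. The epoch count follows
   `floor((T − L)/step) + 1` with `step = L(1 − overlap)`; for 300 s this
   gives 599 epochs and for 180 s gives 359. Reports of such designs
   sometimes quote `T/step` (600) or `T/L` (180) instead; the convention
   here is the one that never lets a window run past the end of the data,
   and both the epoch length and the overlap are exposed per call rather
   than hard-coded.
2. **Re-referencing.** Every EEG channel has the mastoid average
   `0.5(M1+M2)` subtracted. The implicit CZ reference is first
   reconstructed as an all-zero channel so that it survives as
   `−0.5(M1+M2)`; the EOG channel is deliberately left in its original
   reference, since its job is to measure ocular potentials, not the scalp
   field. A state flag guards against double application.
3. **Artifact rejection.** Epochs whose baseline-corrected LVEOG trace
   exceeds ±50 µV are dropped (ocular artifacts; blinks are an order of
   magnitude above this threshold). Manual screening for EMG and motion is
   replaced by a deterministic surrogate: an epoch is dropped when, on the
   analysis electrodes (FZ, OZ by default), its peak amplitude exceeds
   100 µV or its >20 Hz high-passed RMS exceeds 15 µV; an explicit
   user-supplied drop list is also honoured. Each dropped epoch records
   exactly one reason. Because screening is meant to *maximize* the epochs
   available at the electrodes of interest, a floor (`min_retained`, default
   2) restores the least-contaminated amplitude-rejected epochs in the rare
   session that would otherwise be lost entirely; EOG rejections are never
   restored.
4. **Bad-channel interpolation.** Channels flagged bad are rebuilt
   sample-wise by a spherical spline on the unit-sphere montage: the
   classical g-function `g(x) = (4π)⁻¹ Σₙ (2n+1)/(n(n+1))ᵐ Pₙ(x)` with
   stiffness `m = 4`, the Legendre series truncated at 50 terms, and ridge
   smoothing `λ = 1e−5` on the diagonal of the interpolation system. These
   are conventional values for this algorithm family; `λ = 0` recovers
   exact interpolation at the good sites, and constants are reproduced
   exactly for any `λ` because the constant sits in the spline's null
   space. Good channels are never touched.
5. **Spectral estimation.** Per-epoch one-sided periodograms via FFT with a
   Hamming window and power-gain compensation (division by the mean squared
   window), giving 1 Hz bins for 1-second epochs and making the spectrum
   sum to the windowed-signal variance. Band power is the mean of the
   band's bins, edges inclusive (theta 4–7, alpha 8–13, low beta
   14–20 Hz). Mean band power averages the *linear* per-epoch powers over
   retained epochs and converts to dB re 1 µV² at the end; power
   variability is the SD over retained epochs of the linear per-epoch
   powers, likewise converted to dB. Averaging linear power first is
   standard Welch practice; dB referencing to 1 µV² is the convention that
   makes typical resting band powers land in the 10–30 dB range. Degenerate
   zero power or spread is floored at a −300 dB sentinel instead of
   erroring, keeping result tables total.
6. **Inference.** Fully-within ANOVAs with up to three two-level factors
   (Environment × Resting State × Electrode for rest; Environment × Task ×
   Electrode for PASAT against eyes-open rest; electrode-collapsed
   Environment × Condition for power variability; one-way Environment for
   PASAT scores). Each effect is tested against its own subject×effect
   error stratum (`stats::aov` with an `Error()` term), so with two-level
   factors every effect has df (1, n−1) and no sphericity correction is
   needed. Each F is augmented with partial eta squared
   `F·df1/(F·df1+df2)` and the BIC approximation of the Bayes factor
   `B01 = sqrt(n^df1 (1 + F·df1/df2)^(−n))`, `B10 = 1/B01`, with
   `n` = the number of subjects. That choice of `n` is forced by the
   analytic anchor `B01(F=0) = √n` (4.58 at n = 21), which the published
   tables this package validates against reproduce exactly. Posterior
   probabilities are `P(H0|D) = B01/(1+B01)`; evidence is labelled on the
   Jeffreys scale (weak [1, 3.16), substantial [3.16, 10), strong
   [10, 31.62), very strong [31.62, 100), decisive ≥ 100, applied to
   max(B01, B10)). Weather correlations use Pearson r, the F-equivalent
   `r²(n−2)/(1−r²)`, and Bonferroni multiplication of p by the six tests
   (capped at 1), the reading consistent with published "p = 1.00" entries.
7. **Effect sizes.** The repeated-measures Hedges' g standardizes the mean
   paired difference by the *average of the two condition SDs* and applies
   the small-sample correction `J = 1 − 3/(4(n−1)−1)`. The average-SD
   standardizer keeps g comparable with between-subject designs in the
   literature pool; the cited "bias-corrected standardized difference" does
   not pin a variant, and this is the conservative common choice. The
   standard error uses the paired-design normal approximation
   `var(d) = (1/n + d²/2n)·2(1−ρ)` with the observed cross-condition
   correlation (or an assumed ρ, default 0.7, for literature records that
   omit it), and 95% CIs are `g ± 1.96·se`. Literature records reported as
   paired t convert via `g = J·t/√n`, and single-df F via `t = √F` with an
   explicit direction sign. Pooling is fixed-effect inverse-variance with
   `se = 1/√Σw`. Published observed-effect CIs in this design family are
   sometimes far narrower than any subject-level formula yields (plausibly
   epoch-level bootstraps); those widths are not reproduced here, and the
   comparison against meta-analytic estimates is therefore made
   qualitatively — CI overlap, sign agreement, magnitude order — which is
   also all the published narrative uses.

## The synthetic-data generator

The generator exists so that every stage above is testable end-to-end
without human recordings. Each session is a sum of per-band narrowband
processes — complex-Gaussian spectra confined to the band's bins, scaled so
the time-domain RMS is *exact* — plus a 1/f background over 1–45 Hz,
scheduled artifacts, and an optional pure tone for calibration checks.
Defaults define the emulated study conditions and were fixed once, before
any downstream results were inspected:

| parameter | default | rationale |
|---|---|---|
| subjects, rate | 21, 256 Hz | the emulated design |
| durations | 300 s rest, 180 s PASAT | retained recording lengths |
| base band RMS (µV) | theta 6, alpha 5.5, beta 3 | ~20 µV total scalp RMS, a realistic mobile-EEG level that keeps clean epochs clear of the 100 µV screen |
| eyes-closed multipliers | theta 1.15, alpha 1.5, beta 1.1 | alpha 20·log10(1.5) ≈ 3.5 dB enhancement, the classic eyes-closed effect; weak theta/beta analogues |
| PASAT multipliers | alpha 0.75 | task alpha suppression ≈ −2.5 dB vs eyes-open rest |
| outdoor multipliers | beta 1.08 | the small outdoor beta shift (~0.7 dB) |
| topography gradients | theta +0.14, alpha −0.14, beta −0.08 | frontal theta and posterior alpha/beta dominance of ~1–2 dB between FZ and OZ |
| subject / session sdlog | 0.30 / 0.10 | ≈2.6 dB between-subject and ≈0.9 dB between-session power spread |
| 1/f exponent, scale | 1.0, 10 µV RMS | eyes-closed alpha band SNR ≈ 5:1, typical resting spectra shape |
| blinks, EMG | 10/min, 2/min | calibrated so ≈467 of 599 resting epochs survive the default screens — the only generator calibration target, and an explicitly prescribed one |
| blink shape | 0.2 s biphasic, 150 µV peak on LVEOG | reliably trips the ±50 µV EOG threshold; scaled on the scalp by a frontal-to-posterior gradient |
| bad channels | p = 0.15 per session | occasional flat-lined channel, exercising interpolation |

Subject effects are log-normal amplitude multipliers shared across a
subject's sessions (log-normality gives dB-domain normality, matching the
ANOVA's assumptions); session jitter adds subject-by-condition variability,
which is what the within-subject error strata estimate. All randomness
derives deterministically from the design seed (per-session sub-seeds below
2³¹), so identical designs and seeds are byte-identical.

What the generator does *not* emulate: amplifier electronics and the
125→250→256 Hz resampling chain, Bluetooth dropouts, spatially coherent
source topographies (channels are independent draws apart from their gain
profiles), non-stationary drowsiness or adaptation effects, and real EMG
spectra (bursts are band-limited 21–45 Hz noise). Green tests therefore
demonstrate that the *analysis* behaves correctly on data with the assumed
statistical structure — they do not validate the generator against real
mobile-EEG recordings.

## Numerical choices and degenerate inputs

- dB floor at −300 for zero power or zero spread, rather than −Inf/error.
- ANOVA F for a zero-variance effect with zero error variance is defined
  as 0 (no evidence of an effect), and capped at 1e12 when the error
  stratum alone is degenerate; Bayes factors are evaluated in the log
  domain so very large B10 (10⁵ and beyond) stay accurate.
- Correlation F-equivalents are capped at 1e12 for |r| = 1.
- The EDF writer rounds each channel's physical range outward to the
  header's 2-decimal precision so no sample clips; round-tripping is exact
  to 16-bit quantization.
- Tie-breaks: Jeffreys bins are half-open on the right, so B = 10 is
  "strong" and B = 100 "decisive"; band edges are inclusive at both ends
  at the 1 Hz resolution.

## Problem sizes used by the test suite

The statistical contracts (Bayes factors, posteriors, eta squared, Jeffreys
labels, effect-size algebra) are exact-arithmetic checks and run in
milliseconds. Signal-level property tests use short sessions (2–60 s);
the parameter-recovery study runs the full pipeline at the complete n = 21
within-subjects design over 20 seeds per arm with 30-second resting
sessions — enough for ≈59 epochs per session, which pins band power well —
as the package's chosen balance between statistical resolution and a test
suite that completes in a few minutes. The full 300 s / 180 s study-scale
durations are the generator defaults and run through the identical code
path.

## Known limitations

- Only two-level within-subject factors (the designs analysed here need
  nothing more); no sphericity machinery, no mixed models, no prior-based
  Bayes factors.
- Fixed-effect pooling only; no heterogeneity statistics or random-effects
  meta-analysis.
- The observed-g confidence intervals use the subject-level normal
  approximation and are wider than epoch-resampling intervals would be.
- The amplitude/HF-RMS screen is a surrogate for expert visual rejection;
  its thresholds (100 µV, 15 µV) are sensible defaults, not a validated
  classifier.
- EDF support is the minimal continuous 16-bit variant (no EDF+
  annotations, single common sampling rate).
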