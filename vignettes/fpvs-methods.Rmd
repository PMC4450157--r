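---
title: "Frequency-tagging analysis of FPVS oddball EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagging analysis of FPVS oddball EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fpvs` implements the analysis logic of fast periodic visual stimulation
(FPVS) oddball EEG experiments: stimuli stream at a fixed base rate (6 Hz
by default) under sinusoidal contrast modulation, and every fifth stimulus
belongs to a deviant category, so any neural process that discriminates the
deviant category — and generalises across its exemplars — produces energy at
exactly 6/5 = 1.2 Hz and its harmonics in the EEG spectrum. Because the
response frequency is known in advance and the analysis window spans an
integer number of cycles, detection reduces to comparing single DFT bins
against their local noise neighbourhood. This vignette describes the models,
the tunable parameters, the synthetic cohort generator, and the numerical
and design choices, in the package's own words.

## The stimulation model

A sequence is: pre-baseline (2 s of grey screen), linear fade-in (2 s),
full-contrast stimulation (20 s), linear fade-out (2 s), post-baseline
(2 s) — 28 s in all. Within the stimulation period the on-screen contrast is
a raised cosine of time from fade-in onset,

$$c(t) = \tfrac12\bigl(1 - \cos 2\pi f_\text{base} t\bigr) \cdot d(t),$$

where $d(t)$ is the linear contrast-modulation depth ramp (0→1 over the
fade-in, 1 during the full-contrast window, 1→0 over the fade-out). The
raised cosine is the unique sinusoid that starts at 0% contrast (grey) at
each cycle onset and reaches full contrast midway through the cycle
(83.33 ms at 6 Hz); descriptions of the design as "sinusoidal contrast
modulation from grey" admit exactly this form, which is why the package
fixes it. One continuous cycle count runs across fades and full-contrast
window — the alternative (restarting the oddball phase at the full-contrast
onset) is not distinguishable from published descriptions, and a continuous
count is what a presentation loop naturally produces. With the defaults the
20-s window holds 120 stimuli, 24 of them oddballs, and both 6 Hz and
1.2 Hz fall exactly on the 0.05 Hz bin grid of a 20-s window.

Acquisition-side triggers are modelled as one trial-start marker plus one
marker per cycle minimum (0% contrast), coded base/oddball; sample indices
round half away from zero for platform determinism.

`phase_scramble_image()` implements the control-stimulus transform:
randomise the 2-D Fourier phases of an image while preserving its amplitude
spectrum. Random phases are taken from the Fourier transform of a
white-noise image, which is Hermitian-symmetric by construction, so the
output is exactly real; self-conjugate bins (DC and Nyquist combinations)
keep their original values, so a constant image is returned unchanged and
total power is preserved to machine precision.

## The synthetic cohort generator

The generator exists because the package's statistics need data with the
right structure: tagged harmonic responses on plausible scalp topographies
over 1/f background noise. It deliberately does *not* attempt biophysical
realism (no head model, no eye/muscle artifacts, no spatial noise
correlation — the quantification below is strictly per-channel, so spatial
correlation would not change any tested quantity).

Each subject's recording is:

* **Background noise** per channel: Gaussian noise with power spectrum
  $P(f) \propto 1/f^{\alpha}$ on 0.1–100 Hz plus a small white floor,
  synthesised by shaping white noise in the frequency domain. Defaults:
  $\alpha = 1$, 2 µV RMS pink, 0.1 µV RMS white floor. The RMS was chosen,
  before any testing, so that the default component amplitudes land in the
  published range of infant neighbour-bin SNRs (grand-average oddball SNR
  in the low single digits, single-sequence base-rate SNR near 10); it is a
  free parameter of the simulation, not a fitted value.
* **Tagged components**, present only during stimulation and scaled by the
  contrast-depth ramp during fades: a base-rate component (6 Hz, 1 µV at
  Oz with 0.8 at O1/O2, second harmonic 0.25 µV) modelling visual
  synchronization, and an oddball component (1.2 Hz, 0.15 µV at P8 with
  0.55 relative weight at the homologous left channel P7 and 0.3 at the
  occipito-parietal neighbours; second harmonic 0.06 µV) modelling the
  category response. Amplitudes in µV are free parameters — no absolute
  amplitudes are published for the infant data — so the package's tests
  target *relative* and *recovery* properties, never absolute published
  SNRs.
* **Between-subject variability**: one lognormal multiplicative factor per
  component per subject, sigma 0.5, chosen to reproduce the order of the
  published individual SNR spread (roughly 0.5–6 at the oddball site);
  sequence counts drawn uniformly from 5–12 (single-condition cohorts) or
  2–7 per condition (two-condition cohorts, matching an average near 4.5).
* **Condition**: `"scrambled"` silences the oddball components (amplitude
  0) while keeping the base-rate response — phase-scrambled stimuli keep
  the power spectrum but carry no category structure. Random draws do not
  depend on condition, so natural/scrambled cohorts with one master seed
  share noise realisations subject by subject; `scrambled_twin()` exploits
  this to derive the scrambled recording by exact component subtraction.

The native rate is 512 Hz (typical of active-electrode amplifiers, and
high enough that the 0.1–100 Hz band sits well inside Nyquist), so the
downsampling stage performs genuine rate reduction.

What passing tests on these data do show: the pipeline recovers known
amplitudes exactly in the noise-free limit, its SNR/Z statistics are
correctly calibrated under a pure-noise null, and cohort-level inference
detects effects of the configured size with the configured variability.
What they cannot show: robustness to real artifacts (blinks, movement),
to non-stationary noise, or to montage imperfections.

## Preprocessing chain

In order: FFT band-pass filter (0.1–100 Hz) → Fourier resampling to
250 Hz → segmentation into 28-s epochs (2 s before each trial-start
trigger) → optional interpolation of a bad channel → common average
reference → crop to the 20-s full-contrast analysis window → per-sequence
QC. Each step records itself in the recording's provenance chain.

Numerical choices:

* The "FFT band-pass" is a frequency-domain mask with raised-cosine
  transitions (0.1 Hz wide at the low edge, 5 Hz at the high edge); a
  brick-wall mask rings. Passband gain is exactly 1, so bin-aligned tagged
  components are untouched.
* Resampling truncates the discrete spectrum at the new Nyquist and
  inverse-transforms at the new length — exact for band-limited signals.
  The recording must span a whole number of samples at the target rate
  (whole-second recordings always do). Inside `preprocess_subject()` the
  filter and the resampler share one FFT round trip; a test proves the
  fused path equals the two public operations to ~1e-13.
* Channel interpolation is an inverse-distance-weighted mean of the 3
  nearest montage neighbours (both the method and the neighbour count are
  configurable; published pipelines rarely state theirs).
* The analysis window is `epoch[4 s, 24 s)` — pre-baseline plus fade-in
  skipped — giving exactly 24 oddball cycles, so the tagged bins are
  leakage-free by construction.
* QC implements the base-rate synchronization criterion: a sequence is
  rejected only when the neighbour-bin SNR at the base rate is below
  threshold (default 2) at **all** of Oz, O1, O2. The inequality is strict
  with a 1e-9 guard so a value exactly at threshold is never rejected by
  floating-point rounding. Exclusions that real studies apply by
  inspection (technical problems, electrode off, no fixation) enter as
  external annotations. A separate channel-median spectrum-RMS outlier
  flag (`flag_noisy_sequences()`, default 3x the cohort median) marks
  globally noisy sequences for inspection but never drops them — published
  pipelines give no numeric rule for that exclusion.

## Spectral quantification

Per subject, retained analysis windows are averaged in the time domain
(phase-locked activity survives; background shrinks as $1/\sqrt{n}$) and
Fourier-transformed with a rectangular window, no taper, no zero padding,
no detrending: the integer-cycle crop makes the tagged bins exact, and a
taper would only smear them. Amplitudes are in µV of sinusoid peak
($2|X_k|/N$); the bin spacing is $1/20\,\text{s} = 0.05$ Hz.

Two neighbour-bin statistics are computed at every bin $k$ from the 20
surrounding bins (10 per side, excluding the immediately adjacent bin,
offsets ±2…±11):

* **SNR**: amplitude divided by the neighbour mean — 1 is the noise level,
  and SNR − 1 expressed in percent is the "signal increase" (an SNR of
  2.56 is a 156% increase).
* **Z-score**: amplitude minus neighbour mean, divided by the neighbour
  *sample* standard deviation (n − 1 = 19), tested one-tailed against
  1.64. Published descriptions do not say whether the sample or the
  population SD was used (2.6% difference at n = 20) nor whether the Z
  neighbourhood excluded adjacent bins; both toggles are exposed
  (`n_per_side`, `skip_adjacent`), and the defaults — sample SD, same
  neighbourhood as the SNR — keep a single noise-bin definition.

Bins without a full neighbourhood, with a zero neighbour mean (SNR) or
zero neighbour SD (Z) are flagged undefined rather than propagating
infinities. Amplitude-bin noise is Rayleigh-like, so under a pure-noise
null the mean SNR sits slightly above 1 (~1.015) and P(Z > 1.64) between
0.02 and 0.10, not exactly 0.05 — the null-calibration test asserts those
calibrated ranges.

## Group-level inference

Grand-averaged spectra are per-bin means of the subjects' amplitude
spectra (averaging in the amplitude domain, after each subject's FFT);
grand-average SNR/Z are then computed from the averaged spectrum. Both
tracks — grand-average metrics and per-subject metrics — are emitted,
mirroring standard two-track reporting.

Tests: channel-wise Z converted to a one-tailed normal p and compared to a
Bonferroni-corrected level (0.05/32 = 0.0015625 for a whole 32-channel
montage); one-sample t-tests of individual SNRs against the noise level 1;
paired t-tests for right-vs-left (P8 vs P7) and natural-vs-scrambled
contrasts; and per-subject tallies of Z > 1.64 with a fallback count of
subjects significant on some other channel. Tail conventions follow the
printed p-values of the literature this design comes from: vs-noise and
lateralization tests are directional (one-tailed flags), condition
contrasts two-tailed; both tails are always reported and the flag is
configurable. Thresholds are strict inequalities throughout ("below 2",
"Z > 1.64"). All t and normal tail probabilities come from `stats::pt()` /
`stats::pnorm()`, cross-checked in the tests against adaptive quadrature
of the densities.

## Experiment runners and reproducibility

`run_experiment1()` (single condition, default 15 subjects × 5–12
sequences) and `run_experiment2()` (paired natural/scrambled, default 10
subjects × 2–7 sequences per condition) orchestrate
simulate → preprocess → spectra → statistics and emit a report bundle
(cohort table, test table, QC log, grand spectrum table, oddball
topography table as TSV; manifest with seed, config hash and versions as
JSON; a markdown summary whose every number comes from those tables).
Everything is driven by one master seed: per-subject seeds derive from it,
so report bundles are bit-reproducible.

## Known limitations and honest failure modes

* Synthetic amplitudes are free parameters; only structure, calibration
  and recovery — not published absolute SNR/Z values — are testable.
* At the published study sizes the *two-condition* paired contrast is
  intrinsically low-powered: with 10 subjects, 2–7 sequences per
  condition and a 0.15 µV oddball amplitude, the natural-vs-scrambled
  paired t at the oddball site centres near t ≈ 2.5–3 on 9 degrees of
  freedom — the same region as the published t(9) = 2.969, p = 0.016 —
  which replicates at two-tailed α = 0.05 in only about half of simulated
  cohorts. The package reports this honestly: the corresponding
  cohort-recovery expectation in the acceptance tests fails (10/20 master
  seeds), while the single-condition effects (grand Z > 1.64, t vs noise,
  right > left lateralization) and the scrambled-null check succeed in
  20/20. A replication-rate criterion of 90% would require roughly twice
  the published effect-to-noise ratio.
* Z-scores in near-zero stopband bins (above the filter's upper edge) are
  numerically meaningless ratios of rounding noise; they are defined but
  should not be interpreted. Tagged frequencies never lie there.
* Problem sizes used by the test suite are the package's own choices:
  the null calibration uses 200 simulated noise epochs; the type-I
  calibration uses 100 cohorts of 10 subjects × 2 sequences at a 500 Hz
  native rate; cohort recovery uses the full experiment defaults over 20
  master seeds.
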