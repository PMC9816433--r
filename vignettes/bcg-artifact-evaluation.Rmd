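---
title: "Evaluating BCG artifact correction with ground-truth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating BCG artifact correction with ground-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgpreserve)
```

## The problem

EEG recorded during simultaneous fMRI is contaminated by two large
artifacts. The gradient artifact (GA) is induced by gradient switching: it
is essentially deterministic, periodic at the repetition time (TR), and one
to two orders of magnitude larger than the EEG. The ballistocardiographic
(BCG) artifact is driven by cardiac-related electrode motion in the static
field: a multi-harmonic waveform starting roughly 210 ms after each R wave,
with power concentrated between 1 and 15 Hz, variable from beat to beat,
and with a characteristic polarity inversion across the scalp midline.

The GA is removed well by average artifact subtraction (AAS). For the BCG,
a family of corrections is in routine use — AAS on cardiac epochs, the
optimal basis set (OBS), independent component analysis (ICA), the
combinations OBS-ICA and AAS-ICA, the component-space PROJIC variants, and
ICA feature extraction (IFE), which *retains* alpha-related components
instead of removing artifact components. What matters scientifically is not
how much artifact a method removes but how much functional EEG content it
preserves. On real recordings that question is hard to answer because the
clean EEG is unobservable. This package makes the question testable by
simulation: every subject is generated with a known clean signal, known
artifacts, and a known coupling between alpha power and a synthetic BOLD
grid, so preservation can be measured exactly.

## The simulator

`sim_config()` / `assemble_subject()` generate one subject as

* **Clean EEG** — per channel, an independent 1/f background
  (spectrally shaped white noise, exponent 1, RMS 5 µV) plus a shared alpha
  source: a 10-Hz oscillator whose amplitude follows alternating 20-s
  eyes-closed (EC) / eyes-open (EO) blocks (EC amplitude √3 × EO, i.e. a
  true EC/EO band-power ratio of 3.0), scaled by a posterior-dominant
  topography. The oscillator's phase performs a random walk (diffusion
  2 rad²/s). The diffusion term matters: a phase-coherent sinusoid whose
  period divides both the TR (2 s) and the mean RR interval would be
  spuriously phase-locked to both artifact grids and would be subtracted
  by the very templates under test, which no physiological alpha rhythm
  would be. The instantaneous band power is unaffected (amplitude² / 2),
  so the spectral ground truth stays exact.
* **ECG** — a QRS-like waveform (sharp R peak, Q/S troughs, broad T wave)
  at R times drawn with RR = 0.9 ± 0.05 s (uniform jitter); the R-peak
  train is returned as ground truth.
* **BCG artifact** — one damped multi-harmonic cycle per heartbeat starting
  210 ms after the R peak. The harmonic multiples {5, 6, 7, 9, 12} of the
  cardiac fundamental (≈1.11 Hz) with relative amplitudes {1, 1, 1, 2, 1}
  and damping constant 0.25 s concentrate the artifact's spectral mass in
  the theta and slow-beta bands and place a strong line at ≈10 Hz. This
  reproduces the artifact's hallmark behaviour: broadband power inflation
  strongest in theta/slow-beta, and occipital EC-EO alpha reactivity masked
  by alpha-band artifact power. Per-cycle amplitude jitter is ±10%; the
  channel topography carries a left-right polarity inversion, which is what
  the topography criterion of the component scoring looks for. ≥ 95% of
  artifact power lies within 1–15 Hz.
* **Gradient artifact** — a deterministic slice-frequency harmonic comb
  (30 slices per 2-s TR) repeated identically every TR at 50 × the clean
  RMS. Real GA drifts slightly; the default is perfectly periodic, which is
  the regime the AAS oracle requires. GA residual structure after AAS is
  therefore optimistic relative to real data.
* **BOLD grid** — 10 × 10 × 10 voxels × 120 volumes at TR 2 s. 10% of
  voxels follow β·z(HRF ⊛ alpha power) + AR(1) noise with β = −1
  (alpha suppresses BOLD), AR coefficient 0.3, innovation SD 1. A separate
  `bold_coupled_seed` lets a cohort share one coupled mask for group-level
  inference.

Everything is seeded: `assemble_subject()` is deterministic given
`cfg$seed`, and `cohort_configs()` derives per-subject seeds from one
master seed.

### What the simulator does *not* emulate

Head motion, blinks, helium-pump noise, electrode drift, beat-to-beat BCG
*waveform* (as opposed to amplitude) variability, the ~200-ms variability
of the BCG delay itself, spatially correlated BOLD noise, and real fMRI
spatial preprocessing. Tests passing on these simulations therefore
certify the algorithms' contracts (cancellation oracles, selection logic,
calibration), not their performance on any particular real recording.

## The pipeline

`run_cohort()` chains the stages exactly as an analysis of real data
would: GA-AAS (5-volume sliding window) → 1–50 Hz zero-phase band-pass →
QRS detection on the simulated ECG → one of the BCG corrections → 2-s
epochs with peak-to-peak rejection → band power, percent change, EC-EO
alpha ratio → repeated-measures ANOVA with Bonferroni post-hocs against
the clean "outside-scanner" reference → alpha-predictor GLM against the
synthetic BOLD. The clean component of each simulation plays the role of
the outside-scanner recording: it is the same brain signal without
artifacts, which is precisely what that reference approximates in a real
study.

## Parameters that matter, and why these defaults

| parameter | default | role |
|---|---|---|
| band-pass | 1–50 Hz | analysis band; bands: delta [1,4), theta [4,8), alpha [8,13), slow beta [13,18), fast beta [18,31), gamma [31,50] Hz |
| epoch length | 2 s | 0.5-Hz spectral resolution; one epoch per TR |
| BCG delay | 0.21 s | onset of the artifact epoch after the R peak |
| GA window | 5 volumes | sliding-window template width |
| BCG AAS window | 21 cycles | template adaptivity vs. stability; the GA-style window is specified only for the GA, so the BCG window is our choice |
| OBS components | 4 | principal components regressed out per channel |
| Savitzky–Golay | frame 11, order 5 | smoothing before alpha-peak search in 7–13 Hz |
| rejection threshold | 150 µV peak-to-peak | automated stand-in for visual epoch rejection; a fixed criterion is reproducible where visual inspection is not |
| gamma HRF | mode 6 s, SD 3 s | kernel parameterised by mode and dispersion; unit sum |

The printed integer band edges (1–3, 4–7, 8–12, 13–17, 18–30, 31–50 Hz)
leave the 0.5-Hz bins between bands unassigned; the half-open partition
above assigns every bin deterministically and makes relative powers sum to
exactly 1. The relative-power denominator is the partition total, which
equals the 1–50 Hz total under this partition.

## Numerical and algorithmic choices

* **Filtering** — the band-pass is a 2nd-order Butterworth high-pass
  cascaded with a 4th-order low-pass, both applied forward-backward
  (zero phase). The cascade is numerically safer than a single band-pass
  at a normalized high-pass edge of 0.002 and meets ≥ 20 dB attenuation an
  octave outside the band.
* **Epoch spectra** — rectangular-window FFT (a Hann window is available),
  scaled so the bin sum equals the mean squared amplitude (Parseval).
* **AAS** — templates are unweighted sliding-window means; the unweighted
  choice makes the operator linear in the data, so component-space AAS
  remixed through the mixing matrix equals channel-space AAS exactly
  (the identity PROJIC relies on; per-cycle least-squares scaling is
  available via `scale = TRUE`). Artifact epochs span R + delay − 0.25·RR̃
  to R + delay + 0.75·RR̃ (RR̃ = median RR); overlapping epochs are
  truncated at midpoints so each sample is corrected once. A consequence
  of any unweighted w-segment template is EEG leakage at 1/√w of the clean
  RMS (≈ 45% for the 5-volume GA window) — the template mean contains the
  EEG of the averaged segments. This is inherent to AAS, not an
  implementation defect, and is why GA-AAS is followed by further
  correction stages in practice.
* **OBS** — per channel, PCA of the aligned artifact-epoch matrix; the
  epoch mean is included as an implicit regressor alongside the leading
  components ("optimal basis set" convention), and the fit uses an SVD
  pseudo-inverse because the mean can lie inside the component span for
  exactly rank-limited artifact families.
* **ICA** — symmetric fixed-point iteration after PCA whitening. The
  kurtosis (cube) contrast is the default: the amplitude-modulated alpha
  source is sub-Gaussian and the logcosh contrast demonstrably fails to
  separate it from Gaussian 1/f background (verified against an
  independent reference implementation on the same mixture). When the
  update cycles without meeting the tolerance — typical when some retained
  components are near-Gaussian noise — the iterate closest to a fixed
  point is kept; results remain seed-deterministic. `thin` estimates the
  unmixing matrix on every k-th sample for long recordings; sources are
  always computed from all samples.
* **Component scoring** — cardiac locking is tested against a null of
  randomly repositioned R trains (199 permutations, p < 0.01); the
  harmonic-spectrum criterion compares periodogram mass at harmonics 1–6
  of the cardiac fundamental (below the alpha band, so a 10-Hz alpha
  component cannot satisfy it via the 9th harmonic) with the half-harmonic
  neighbourhoods (ratio > 2); topography uses the negated correlation of
  left-right (or anterior-posterior) mirror-electrode weights (> 0.5). All
  three must pass — these thresholds are the automated stand-in for the
  manual selection the method family traditionally uses, chosen for
  reproducibility and logged in every report.
* **IFE** — a component is retained iff its source EC/EO alpha ratio
  exceeds 2, its dominant spectral peak (2–40 Hz) falls in 8–12 Hz, and
  the posterior share of its absolute mixing weights exceeds 0.5.
* **Component removal** — removed components' contribution is subtracted
  from the original data, so an empty removal set reproduces the input
  even for rank-reduced decompositions; IFE reconstructs from retained
  components only (it is a feature extractor, not a cleaner).
* **RM-ANOVA** — classical partitioned sums of squares;
  Greenhouse–Geisser epsilon from the double-centered condition
  covariance (Huynh–Feldt available). Degenerate inputs (no condition
  variance) return F = 0 rather than NaN.
* **Predictor construction** — per-epoch alpha power, rejected epochs
  interpolated from nearest neighbours, convolution with the gamma kernel
  under a steady-state assumption (the series is padded with its first
  value, so constant alpha maps to a constant, hence zero after
  centering), sampled on the volume grid and mean-centered. Channel
  selection `"auto"` picks O1 or O2 by the larger EC/EO ratio.
* **GLM** — voxelwise OLS with intercept and linear + quadratic drift
  columns (standing in for the high-pass filtering of fMRI pipelines);
  one-sided test of β < 0. OLS p-values are nominally calibrated under
  white noise; the simulator's default AR(1) BOLD noise mildly inflates
  first-level rejection rates, which is one reason group inference is
  permutation-based. Group level: sign-flip max-statistic permutation
  (exhaustive when 2^n fits the budget, exact p-values), familywise error
  controlled at 0.05.

## Design choices that were genuinely open

* The BCG AAS window (21 cycles) and PROJIC's inner parameters (same as
  the channel-space methods) are documented defaults, not reproductions of
  any reference implementation's unstated choices.
* Event indices are 1-based in memory (R convention) and 0-based in TSV
  event files; EDF+ annotations store seconds. Conversions happen only at
  I/O boundaries.
* The EDF writer digitizes against the header-rounded physical limits
  (rounded outward), so a write-read cycle is exact to 16-bit
  quantization.
* The simulated cohort's "outside" reference is the clean component of the
  same simulation — the closest analogue of an outside-scanner recording
  with identical brain activity.
* Volume count is configurable; the default 120 volumes corresponds to the
  4-minute EC-EO run at TR 2 s.

## Known limitations

* IFE reconstructions contain only alpha-component activity; their
  non-alpha band power is far below physiological levels by construction.
  IFE is evaluated on reactivity preservation and predictor quality, never
  on broadband spectral preservation.
* The AAS EEG-leakage floor (1/√window) bounds how well any sliding-mean
  template can preserve the EEG; per-epoch alpha estimates after AAS carry
  that leakage noise.
* The detectors and thresholds are tuned to desk-scale simulations with
  known ground truth; real recordings with poor ECG quality or atypical
  BCG topographies will need threshold review (every report logs the
  thresholds used).

## Problem sizes used by the test suite

Module tests run subjects of 80–120 s (often at 500 Hz) — large enough for
stable spectra and ICA, small enough to iterate quickly. The end-to-end
checks use 20 subjects of 240 s at 1000 Hz for reactivity recovery and 8
subjects for group-level GLM recovery, mirroring a realistic task-run
length; these sizes are the package's choices for a desk-scale,
fully-reproducible validation.
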