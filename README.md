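# bcgpreserve

Does ballistocardiographic (BCG) artifact correction preserve the EEG
signal it is supposed to rescue? `bcgpreserve` is an R toolkit for
answering that question quantitatively. It targets researchers running
simultaneous EEG-fMRI who need to choose (or validate) a BCG correction
strategy, and method developers who need a reproducible benchmark with
known ground truth.

EEG recorded inside the MR scanner is contaminated by the TR-periodic
gradient artifact (GA) and by the cardiac-driven BCG artifact — a
multi-harmonic waveform peaking ~210 ms after each R wave with power
concentrated in 1–15 Hz, right on top of the physiological bands. The
package implements:

* **Ground-truth simulation** of contaminated EEG-fMRI sessions: 18-channel
  10–20 EEG at 1000 Hz with 1/f background, a posterior alpha rhythm
  (frequency *f* ≈ 10 Hz) whose amplitude follows 20-s eyes-closed /
  eyes-open (EC/EO) blocks with a true EC/EO power ratio
  (A_EC/A_EO)² = 3, a jittered-RR ECG, a cardiac-locked BCG artifact with
  left-right polarity inversion, a TR-locked gradient artifact, and a
  voxel grid whose coupled voxels follow
  y = β·z(HRF ⊛ alpha power) + AR(1) noise with β < 0.
* **Artifact correction**: GA and BCG average artifact subtraction (AAS,
  sliding-window mean templates), optimal basis set (OBS, per-channel PCA
  of aligned artifact epochs with the top 4 components regressed out),
  ICA with automated three-criterion BCG component scoring
  (cardiac locking, harmonic spectrum, topographic polarity inversion),
  the combinations OBS-ICA and AAS-ICA, component-space PROJIC-AAS /
  PROJIC-OBS, and ICA feature extraction (IFE) of alpha components.
* **Spectral preservation metrics**: absolute/relative power over the six
  classical bands, percent change (inside/outside·100 − 100), the
  occipital EC/EO alpha-power ratio, and individual alpha peak / center of
  gravity via Savitzky–Golay smoothing (frame 11, order 5, 7–13 Hz).
* **Inference**: one-way repeated-measures ANOVA with Greenhouse–Geisser
  correction and Bonferroni post-hoc contrasts against an outside-scanner
  reference; EEG-informed fMRI first-level GLM with a negative alpha
  contrast and group-level sign-flip max-statistic permutation.
* **I/O**: minimal EDF+ and BrainVision readers/writers, TSV event files,
  YAML/JSON configs — so the same pipeline runs on real recordings.

## Worked example

```r
library(bcgpreserve)

cfg <- sim_config(seed = 7, duration_s = 240)   # one 4-min task subject
sub <- assemble_subject(cfg)
sub$recording
#> <bcg_recording> 19 channels x 240000 samples @ 1000 Hz (240.0 s)
#>   channels: Fp1 Fp2 F3 F4 F7 F8 Fz C3 C4 P3 P4 Pz T3 T4 T5 T6 O1 O2 ECG
#>   events:   EC_ONSET[6] EO_ONSET[6] RPEAK[266] TR[120]
#>   reference: Cz

# gradient artifact removal, band-pass, QRS detection
eeg <- select_channels(bandpass(ga_aas(sub$recording)$recording),
                       standard_channels())
rpeaks <- detect_qrs(select_channels(bandpass(sub$recording), "ECG"))

# the contaminated recording underestimates alpha reactivity ...
ec_eo_alpha_ratio(epoch_recording(eeg))
#> [1] 1.931376

# ... IFE recovers it (true ratio: 3)
ica <- fit_ica(eeg, n_components = 8, thin = 3, seed = 1)
ife <- ife_alpha(ica)
ife$report$components_retained
#> [1] 6
ec_eo_alpha_ratio(epoch_recording(ife$recording))
#> [1] 3.443505
```

The first ratio (1.93) shows the hallmark attenuation: alpha-band BCG
power inflates the eyes-open denominator, dragging the EC/EO ratio toward
1\. IFE retains a single alpha-related component (here component 6) and
restores the ratio to within the simulation's tolerance of the true
value 3.

Whole-cohort evaluations — per-method band-power tables, percent-change
matrices, RM-ANOVA tables, EC/EO ratios and GLM summaries as CSV — come
from one call:

```r
run_cohort(sim_config(seed = 1), n_subjects = 20,
           methods = c("none", "aas", "obs", "ica", "ife"),
           out_dir = "cohort01")
```

A thin command-line front-end over the same functions is installed at
`inst/scripts/bcg-preserve` (`simulate` and `run-all` subcommands).

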