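Package: bcgpreserve
Title: Ballistocardiographic Artifact Correction and EEG Signal
    Preservation for Simultaneous EEG-fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how well ballistocardiographic (BCG) artifact
    correction preserves the functional content of EEG recorded during
    simultaneous fMRI. Provides a ground-truth simulator of contaminated
    EEG-fMRI sessions (1/f background, block-reactive posterior alpha,
    cardiac-locked BCG artifact, gradient artifact, alpha-coupled BOLD),
    gradient-artifact and BCG correction by sliding-window average artifact
    subtraction (AAS), optimal basis set (OBS), independent component
    analysis (ICA) with automated artifact-component scoring, the combined
    OBS-ICA/AAS-ICA and component-space PROJIC variants, and ICA feature
    extraction (IFE) of alpha activity. Downstream metrics include band
    power and percent change, eyes-closed/eyes-open alpha reactivity,
    individual alpha peak and center of gravity, repeated-measures ANOVA
    with Greenhouse-Geisser correction and Bonferroni post-hoc contrasts,
    and EEG-informed fMRI regression with sign-flip permutation inference.
    Minimal EDF+ and BrainVision readers/writers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
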