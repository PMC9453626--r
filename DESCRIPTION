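Package: swstim
Title: Closed-Loop Auditory Slow-Wave Stimulation and Sleep EEG/ECG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline re-implementation of a windowed closed-loop auditory
    slow-wave stimulation system for NREM sleep (sleep-state gating, a
    first-order phase-locked loop for slow-oscillation phase targeting,
    10 s ON / 10 s OFF window scheduling and pseudorandomized condition
    sequencing) together with the matching analysis chain for EEG
    (Welch spectra, SHAM-referenced percentage change, Hilbert slow-wave
    dynamics, sub-window slow-wave activity, spindle detection and spindle
    probability distributions) and ECG (R-peak detection, per-window RR
    features, RMSSD/SDNN, instantaneous heart rate traces and
    SHAM-referenced change scores), plus repeated-measures correlation,
    circular statistics and multiple-testing utilities.  A synthetic
    polysomnography generator with known ground truth (stage-dependent
    slow oscillations, spindles, 1/f background, REM-like eye movements,
    an RR series with respiratory sinus arrhythmia and a stimulus-locked
    biphasic heart-rate kernel) makes the whole pipeline testable without
    any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
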