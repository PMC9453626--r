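# swstim

Closed-loop auditory slow-wave stimulation for NREM sleep, re-implemented
offline, together with the EEG/ECG analysis chain used to quantify its
effects — all testable end to end on synthetic polysomnography with known
ground truth.

## What problem this addresses

Auditory stimulation during deep sleep can enhance the ~1 Hz slow
oscillations (SO) of NREM sleep, with downstream effects on cardiovascular
regulation. Comparing stimulation strategies fairly requires a *within-night*
design: short windows of 10 s stimulation ON followed by 10 s OFF, with the
condition of each window drawn from a pseudorandomized roster that includes a
silent SHAM control. Delivering tones at a specific SO phase in real time
requires a causal detector of stable NREM sleep plus a phase-locked loop
(PLL) tracking the instantaneous slow-wave phase.

`swstim` is for sleep/EEG researchers who want to study or extend such a
closed-loop system without hardware: it provides

* **`synth_psg`** — a synthetic polysomnography generator (stage-dependent
  EEG with slow oscillations, spindles and 1/f background; an EOG pair with
  REM-like anti-correlated deflections; movement artifacts; an RR-interval
  series with respiratory sinus arrhythmia and a stimulus-locked biphasic
  heart-rate kernel; a rendered ECG), with every injected event logged as
  ground truth;
* **`stim_engine`** — the causal closed-loop algorithm: band-power streams
  (low delta 2–4 Hz, high delta 3–5 Hz, high beta 20–30 Hz), a beta-power
  threshold calibrated on the first 10 min of detected NREM, EOG
  anti-correlation and movement gates, a slow-wave-sleep delta gate, a
  first-order PLL targeting 50° (up-phase) or 230° (down-phase), window
  scheduling and per-condition tone planning (UP, DOWN, ISI1 variants,
  ENVELOPE, BINAURAL BEATS, SHAM), plus audio rendering;
* **`eeg_metrics`** — Welch spectra (4 s Hann, 50 % overlap), the
  SHAM-referenced change `%PSD = 100·(PSD_cond − PSD_sham)/PSD_sham`,
  Hilbert slow-wave dynamics (0.5–2 Hz analytic amplitude), 5 s sub-window
  SWA, spindle detection (Chebyshev 10–16 Hz, 2×–5× mean-envelope
  thresholds) and the 2 s-bin spindle probability distribution,
  baseline-SWA pairing, and the early/late night split;
* **`ecg_metrics`** — R-peak detection, per-window RR extraction, RMSSD /
  SDNN / RR extrema, continuous instantaneous heart rate `IHR = 60/RR`
  (shape-preserving interpolation, last 2 s excluded) and
  `%IHR = 100·(IHR − meanHR_sham)/meanHR_sham` against the closest SHAM
  window within 5 min;
* **`stats`** — repeated-measures correlation (within-subject centring,
  `df = N − k − 1`), Benjamini–Hochberg and Hochberg adjustments, circular
  statistics, paired contrasts — implemented from their definitions.

## The core algorithm

The phase convention is `signal ∝ sin(φ)`: 0° at the positive-going zero
crossing, 90° at the SO peak, 270° at the trough. The engine band-passes the
EEG causally to 0.5–2 Hz (zero phase response at the 1 Hz geometric band
centre), normalises amplitude with a running RMS tracker, and updates a
first-order loop

    e[k]  ← lowpass( x̂[k] · cos θ[k] )          # ≈ sin(φ − θ)/2
    θ[k+1] = θ[k] + 2π f₀ Δt + K · e[k] · Δt      # f₀ = 1 Hz

A trigger fires whenever θ crosses the target phase while the loop is locked
(smoothed error below threshold with sufficient tracked amplitude).
Stimulation windows open on a trigger only during detected stable NREM —
10 min uninterrupted for the first episode, 3 min thereafter — with beta
power below its calibrated threshold, no recent movement, no EOG
anti-correlation, and delta power above its calibration quantile.

## Worked example

```r
library(swstim)
cfg <- run_config(duration_h = 0.5, seed = 4)   # 30 min synthetic night
res <- run_pipeline(cfg)

print(res$hypnogram)
#> <hypnogram> 90 epochs (0.50 h): WAKE=9 N1=3 N2=33 N3=45 REM=0

head(res$windows[, c("window_id", "condition", "on_start", "valid")], 4)
#>   window_id      condition on_start valid
#> 1         1 BINAURAL_BEATS 837.6270  TRUE
#> 2         2           DOWN 866.9892  TRUE
#> 3         3      ISI1_High 887.3329  TRUE
#> 4         4           SHAM 907.5489  TRUE

table(res$windows$condition)
#> BINAURAL_BEATS  DOWN  ENVELOPE  ISI1_High  SHAM  UP
#>              7     7         7          7     6   7

print(res$rr)
#> <rr_series> 1799 beats, mean RR 1000.5 ms (60.0 bpm)
```

The first ON window opens at 837.6 s: sleep onset takes ~4 min of the
hypnogram and the engine then requires 10 min of uninterrupted detected NREM
before stimulating. Conditions are balanced (counts differ by at most one)
because the sequencer reshuffles only after a full block. The RR series
averages 1000.5 ms because the generator's default heart rate is 60 bpm.
`res$dynamics`, `res$swa`, `res$spindle_prob`, `res$hrv`, `res$ihr_change`
and `res$stats` hold the tidy metric tables; with `out_dir` set they are
written as CSV next to a JSON run manifest. A 30 min demo night contains
only ~7 windows per condition, so its per-condition traces are noisy; the
test suite's recovery experiments use 100+ windows.

## Vignette

`vignettes/closed-loop-slow-wave-stimulation.Rmd` documents the model
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, the numerical choices,
and known limitations.
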