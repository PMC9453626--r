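---
title: "Closed-loop auditory slow-wave stimulation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop auditory slow-wave stimulation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swstim)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
data emulate, the numerical choices made where the design was open, and
what the validation does and does not show.

## 1. The system being modelled

During NREM sleep, the EEG is dominated by slow oscillations (SO,
0.5–2 Hz). Brief auditory stimuli presented at specific SO phases can
enhance or perturb slow-wave activity (SWA), and these cortical effects
couple to cardiac autonomic regulation on a timescale of seconds. The
within-night design implemented here alternates 10 s stimulation ON and
10 s OFF windows; each window carries one condition from a pseudorandomized
roster — phase-targeted bursts (UP at 50°, DOWN at 230°), rhythmic 1 s
trains (ISI1 at constant 45 dB or 42.5 dB, or with the ramped plan 40, 40,
42.5, 42.5, 45, 45, 45, 45, 42.5, 42.5 dB), 10 s amplitude-modulated pink
noise (ENVELOPE), 400/401 Hz binaural beats, and a silent SHAM — so that
every contrast is made within the same sleep period against SHAM windows
scheduled identically but without sound.

All event times are seconds from recording start; intervals are half-open
`[start, end)`. Phases use the sine convention — signal ∝ sin(φ), 0° at the
positive-going zero crossing, 90° at the SO peak, 270° at the trough — so
50° lies on the late ascending phase and 230° on the descending phase.

## 2. The synthetic night

`generate_hypnogram()` builds ~90 min sleep cycles in 20 s epochs (N3-rich
early cycles, REM lengthening across the night, a sleep-onset latency of a
few minutes). `generate_eeg()` then synthesises, per stage:

* an SO component: 0.5–2 Hz narrowband noise at a stage-dependent RMS
  amplitude (N3 80 µV, N2 40 µV, N1 5 µV, 0 in WAKE/REM), slowly
  amplitude-modulated (±30 % at 0.05 Hz). A `sinusoid` preset replaces this
  with a clean 1 Hz sine — used wherever the analytic phase must be known
  exactly, as in the phase-locking validation;
* delta (2–4.5 Hz) and beta (20–30 Hz) narrowband components whose
  stage-dependent amplitudes (delta high in NREM, beta high in wake) carry
  the information the online NREM detector relies on;
* Poisson-placed spindles in N2 (rate 2/min; N3 half) with carriers drawn
  from 11–15 Hz and durations from 0.5–1.5 s. Spindles are Tukey(0.5)-
  windowed sinusoids — waxing and waning with a sustained core — so that an
  event's nominal duration is the duration of oscillation near peak
  amplitude. (A Gaussian window was considered and rejected: a "0.5 s"
  Gaussian spindle at three times the background envelope spends under
  0.2 s above the detector's 2×-mean threshold, which makes ground-truth
  durations meaningless for recovery testing and short events
  indistinguishable from band noise.);
* 1/f background noise (15 µV RMS, exponent 1) and occasional large
  movement artifacts (2/h, 400 µV);
* an EOG pair sharing frontal SO leakage, with anti-correlated deflections
  (5/min, 60–150 µV) only in REM.

`inject_stim_response()` multiplies the SO component — and only the SO
component, leaving noise untouched, so recovery tests have a clean target —
by `1 + g(t)` inside each non-SHAM ON window, where `g` ramps linearly to
`peak_gain` over `peak_latency` and then decays as
`exp(−(t − peak_latency)/decay_tau)`. Defaults `peak_gain = 0.8`,
`peak_latency = 0.5 s`, `decay_tau = 3 s` mirror the magnitude and shape of
evoked slow-wave dynamics reported for this stimulation design (an early
peak of roughly +80–100 % that fades within the ON window); the per-tone
evoked amplitude is not otherwise quantified in the literature this package
draws on, so these are free parameters of the generator and documented as
such. An optional `baseline_coupling` scales each window's peak gain by
its 5 s pre-ON slow-oscillation level relative to the across-window mean —
off by default, switched on where a baseline-dependent response must be
recovered end to end. SHAM windows and all samples outside ON windows are
bit-identical to the input.

`generate_rr()` builds the RR series as
`60000/base_hr + RSA + drift + kernel + jitter` (defaults: 60 bpm, 40 ms
RSA at 0.25 Hz, 30 ms drift at 0.005 Hz, 3 ms white jitter) and renders an
ECG by placing a template QRS-T complex at each R time. The
stimulus-locked kernel after each non-SHAM ON onset is biphasic: a half-sine
RR *shortening* (acceleration) of 10 ms over the first 4 s, then a half-sine
RR *lengthening* (deceleration) of 20 ms over the next 8 s — the direction
and timescale observed for auditory stimulation during NREM sleep, with the
deceleration magnitude matching the ~20 ms prolongation of the longest RR
interval reported there. Parameter combinations that could produce
non-positive RR intervals are rejected.

## 3. The closed-loop engine

Everything in the engine is causal: outputs at time `t` use samples at or
before `t`.

**Band power.** A forward-only order-2 Butterworth band-pass, squared, and
averaged over a 2 s sliding window, sampled every 0.5 s. The window length
and step are not dictated by the original real-time design, which is
described only at the level of "spectral power in three bands"; 2 s/0.5 s
balances detection latency against variance and both are configurable.

**NREM detection and gating.** NREM is called where low-delta/high-beta
power exceeds `nrem_ratio_cut` (default 3) and the EOG gate is open. The
first 10 min of uninterrupted detected NREM calibrate (a) the beta
threshold, mean + 2 SD of the calibration beta power — the paper states the
mechanism but no formula, so the conventional outlier rule is used — and
(b) the slow-wave-sleep gate, the 25th percentile of calibration low-delta
power. Eligibility requires the stable-NREM counter (600 s for the first
episode, 180 s after any interruption), movement gate open (|EEG| above
300 µV closes it for 10 s), beta below threshold, and delta above its gate.
The EOG gate closes while the 4 s sliding Pearson correlation of the two
EOG derivations is below −0.6; zero-variance segments count as correlation
0 (open). The EOG cut, movement cut and delta quantile are assumptions
exposed in `detector_config()`, not published values.

**PLL.** A first-order loop at 1 Hz centre frequency runs on the causally
filtered SO band decimated to 100 Hz. The phase detector multiplies the
RMS-normalised input by the quadrature reference `cos θ`, giving
`sin(φ−θ)/2` after a one-pole low-pass (0.8 Hz); the phase advances at the
centre frequency plus `loop_gain × error`. The default `loop_gain = 6 /s`
locks within about two SO cycles and keeps the steady-state error of
off-frequency oscillations (0.8–1.2 Hz) small enough that lock is still
declared. Lock is declared when the
*signed* smoothed error stays below sin(30°)/2 for 2 s with tracked
amplitude ≥ 5 µV — smoothing the signed error cancels the double-frequency
ripple that rectified metrics accumulate, and the amplitude floor keeps
zero or noise-only input from ever locking. Triggers are emitted at each
crossing of the target phase while locked, with linear interpolation of the
crossing instant between decimated samples. A first-order loop tracking an
off-frequency oscillation carries an irreducible static phase offset
(≈ arcsin(2Δω/K)); at the 1 Hz design frequency the delivered-phase
circular mean lands within ~2° of target.

**Scheduling and tones.** When eligible and a trigger at the upcoming
condition's target phase fires (50° for every condition except DOWN's
230°), a 10 s ON + 10 s OFF window opens with the next roster condition;
nothing can start before the OFF window ends, so windows never overlap.
The sequencer shuffles the roster once, exhausts it, and only then
reshuffles — per-condition counts over a night differ by at most one. ISI1
variants place tones at 1 s spacing from the ON onset (window opening is
phase-triggered, then the rhythm is fixed — the narrower reading of the
protocol, adopted because it is the only one realisable without predicting
future phase); UP/DOWN place one 50 ms pink-noise burst per target-phase
trigger during ON; ENVELOPE and BINAURAL BEATS are single 10 s events. A
tone whose burst would cross the ON boundary is dropped, not truncated,
keeping OFF windows stimulus-free. Audio rendering maps dB to amplitude
relative to 45 dB, shapes pink noise as 1/f (−3 dB/octave), and renders
binaural beats as pure tones at 400 and 401 Hz.

## 4. The analysis chain

**Spectra.** `welch_psd()` uses 4 s Hann windows with 50 % overlap
(0.25 Hz resolution), scaled so `sum(power)·Δf` equals the mean square.
Optional normalisation divides each spectrum by its cumulative power up to
30 Hz. `psd_percent_change()` is `100·(cond − sham)/sham` per bin, with
zero-SHAM bins flagged NA.

**Slow-wave dynamics.** The channel is band-passed 0.5–2 Hz with a
zero-phase Hamming-windowed-sinc FIR (order from the 3.3/transition-width
rule, transition = half the lower edge but at least 0.25 Hz — the source
analyses state the filter family but not the order), the analytic amplitude
is taken, averaged per time point across each condition's valid windows
(condition means, matching the structure of the published change formula,
rather than per-window changes averaged afterwards), and expressed as
percentage change against the SHAM per-time-point mean. Only
artifact/arousal-free N2/N3 windows (`mark_valid_windows()`) enter.

**Sub-window SWA.** Each 20 s window splits into ON[0,5), ON[5,10),
OFF[0,5), OFF[5,10); band power per 5 s segment uses 2 s Hann sub-segments,
since the 4 s analysis window cannot tile 5 s — this preserves ≥ 1 SO cycle
per segment at the cost of 0.5 Hz resolution.

**Spindles.** Forward–backward Chebyshev-I band-pass 10–16 Hz, analytic
envelope smoothed over 0.2 s. "Two to five times the mean of the filtered
signal" is read as thresholds on the mean *envelope* (the mean of a
zero-mean band-passed signal is ~0). Candidate events must hold the 2×
threshold for ≥ 0.25 s (brief noise excursions of a Gaussian background
cross 2× freely but rarely persist); boundaries grow outward to the 1.25×
crossing; events merge across gaps < 0.25 s, need ≥ 0.3 s total, and are
rejected if the envelope exceeds 5× the mean (artifact bound). Start, total
duration, peak envelope and the median instantaneous frequency are
reported. `spindle_probability()` marks, for each of ten 2 s bins of every
valid window, whether at least one spindle *started* there (multiple starts
still count once) and divides by the number of valid windows.

**Cardiovascular metrics.** R peaks come from a 5–25 Hz band-pass,
rectification (polarity-robust), 30 ms smoothing and adaptive-threshold
peak picking with a 250 ms refractory period. Only RR intervals with both
bounding peaks inside the 20 s window are used. RMSSD is the root mean
square of successive differences; SDNN uses the sample (n−1) SD — a
convention choice. IHR samples `60/RR` are anchored at the closing R peak
of each interval (the interval-midpoint alternative is exposed as an
option), resampled by a monotone shape-preserving cubic (no overshoot
beyond neighbouring samples — the same contract as a modified-Akima
interpolant), and the last 2 s of each window are dropped because edge
interpolation is unreliable, so traces cover ON plus the first 8 s of OFF.
`relative_ihr()` references each non-SHAM window to the mean heart rate of
the closest SHAM window within ±5 min (inclusive; ties go to the earlier
SHAM — a deterministic rule chosen where the source is silent) and windows
without a qualifying SHAM are dropped.

**Statistics.** `rmcorr()` centres x and y within subject and correlates
the pooled centred values; `df = N − k − 1`, p from the t distribution via
R's `pt` (matches an independent ANCOVA oracle to 1e−10). `bh_fdr()` and
`hochberg_adjust()` implement the step-up adjustments with monotonicity
enforcement. `paired_contrast()` is the paired t-test from its definition,
with degenerate zero-variance differences flagged rather than hidden.
Linear mixed-effects models with Satterthwaite degrees of freedom are
deliberately out of scope; where the original analyses used LMM post hocs,
the pipeline offers paired contrasts with Hochberg correction (condition
post hocs) or BH-FDR (electrode-style maps) as the desk-scale analogue,
and is labelled as such.

## 5. Validation design and problem sizes

The test suite builds every fixture in code under fixed seeds. The
problem sizes are the package's own choices for precise yet fast checks:

* *Phase targeting*: 10 min of the clean sinusoid preset; both targets'
  delivered-phase circular means must land within 10° with circular SD
  below 20° (measured: ~51°/231°, SD < 2°).
* *Scheduler timing*: constructed power streams verify eligibility exactly
  10 min after detected NREM onset and 3 min after an interruption (to
  update-step resolution); a 40 min engine run verifies non-overlap and
  block balance.
* *EEG recovery*: 100 injected ISI1 windows interleaved with 100 SHAM
  windows at 25 s spacing in continuous N3. The injected gain and decay
  are recovered by fitting `A·(1 + a·e^{−(t−t₀)/τ})` to the condition's
  mean-amplitude trace — fitting the amplitude trace rather than the
  %-change ratio halves the estimator noise (the SHAM denominator adds
  variance but no information about the kernel), and across repeated
  simulations the gain estimate is unbiased (±5 %) while τ carries a
  ~+10 % bias from envelope smearing by the analysis filter, well inside
  the 30 % acceptance band.
* *ECG recovery*: 200 stimulated windows with jittered 22–28 s spacing —
  jitter breaks accidental phase-locking between the window grid and the
  0.25 Hz respiratory modulation. The early acceleration is tested as the
  within-window early-vs-late contrast because the SHAM-referenced offset
  of a window is common to both segments and cancels there; the
  deceleration is tested against zero directly. The kernel-off null uses
  Hochberg-adjusted paired contrasts, since testing three HRV features
  uncorrected at α = 0.05 would fail by chance alone in ~14 % of null
  runs.
* *Oracles*: HRV features against brute-force recomputation on 1000 random
  interval sets (1e−12), Welch against direct periodogram averaging
  (1e−10), rmcorr against ANCOVA (1e−10), BH/Hochberg against `p.adjust`,
  circular statistics against the complex mean.
* *rmcorr calibration*: 10,000 null simulations of 20 subjects × 6 pairs,
  vectorised for speed and spot-checked sample-by-sample against
  `rmcorr()` itself; the rejection rate at α = 0.05 must lie in
  0.05 ± 0.01.
* *Spindle recovery*: 30 min of N2 with spindles injected at exactly three
  times the background envelope — calibrated with `spindle_background()`,
  which measures the mean smoothed envelope through the detector's own
  filter, because a different filter's background estimate is biased low
  and silently weakens the intended contrast. Sensitivity and precision
  must both reach 90 %, and the detected 2 s-bin probability distribution
  must reproduce the ground-truth placement.

## 6. What the synthetic data do and do not show

The generator reproduces the *features the pipeline computes on*:
stage-dependent spectra, phase-defined slow oscillations, spindle timing
statistics, REM-like eye movements, movement artifacts, respiratory sinus
arrhythmia and a stimulus-locked cardiac kernel. It does not attempt
realistic sleep microarchitecture (no cyclic alternating pattern, arousal
dynamics, K-complex morphology or stage-transition physiology),
topographic structure beyond two scaled EEG channels, respiratory signals,
or non-stationary noise (electrode drift, sweat artifacts). Passing the
recovery tests therefore demonstrates that the *implementation* is correct
and self-consistent — that the chain recovers what was injected at
realistic signal-to-noise ratios — not that the detector thresholds or the
evoked-response model are accurate for any particular human recording.
Group-level effect sizes from real deposited recordings are not
reproducible at this scale and are not asserted anywhere in the suite.

## 7. Known limitations

* The first-order PLL has a static phase offset for off-frequency slow
  waves; targeting is calibrated at 1 Hz.
* The spindle detector's mean-envelope threshold is estimated over the
  whole recording; heavy artifact contamination would inflate it (real
  deployments would estimate it per stage or per segment).
* HRV on ~20 s windows departs from clinical short-term HRV guidelines by
  construction (the windows are the design's unit of analysis); no
  normal-beat artifact-rejection rule is applied beyond the quality mask,
  which is passed through unchanged.
* The EDF writer/reader implements the 16-bit core of the format (enough
  for round-tripping this package's recordings), not the full EDF+
  annotation model.
* `run_pipeline()` analyses one night; multi-subject repeated-measures
  analyses pool per-night outputs, as the test suite does when it
  exercises `rmcorr()`.
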