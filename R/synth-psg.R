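# Synthetic polysomnography with known ground truth: stage-dependent EEG
# (slow oscillations, delta/beta activity, spindles, 1/f background), an EOG
# pair with REM-like anti-correlated deflections, movement artifacts, and an
# RR series / rendered ECG with respiratory sinus arrhythmia and a
# stimulus-locked biphasic heart-rate kernel.

#' Parameters of the synthetic polysomnography generator
#'
#' Defaults describe a plausible adult night recorded at 500 Hz.  Amplitudes
#' are root-mean-square values in microvolts unless stated otherwise; the
#' slow-oscillation band is 0.5-2 Hz, spindles live in 10-16 Hz.
#'
#' @param sampling_rate Hz (default 500).
#' @param so_freq Hz, centre frequency used by the clean-sinusoid preset.
#' @param so_band slow-oscillation band edges in Hz.
#' @param so_amp_by_stage named RMS amplitude (uV) of the slow-oscillation
#'   component per stage.
#' @param delta_amp_by_stage named RMS amplitude (uV) of 2-4.5 Hz delta
#'   activity per stage (drives online NREM detection).
#' @param beta_amp_by_stage named RMS amplitude (uV) of 20-30 Hz activity per
#'   stage (raised in wake).
#' @param spindle_rate spindle events per minute in N2 (N3 uses half).
#' @param spindle_freq_range Hz, spindle carrier frequencies drawn uniformly.
#' @param spindle_dur_range s, spindle durations drawn uniformly.
#' @param spindle_amp peak envelope amplitude (uV) of injected spindles.
#' @param spindle_amp_jitter fractional uniform jitter of spindle amplitude
#'   (default 0.2; 0 gives identical amplitudes).
#' @param noise_exponent slope alpha of the 1/f^alpha background.
#' @param noise_amp RMS amplitude (uV) of the background noise.
#' @param eog_defl_rate REM eye-movement deflections per minute of REM.
#' @param movement_rate movement artifacts per hour.
#' @param movement_amp artifact amplitude (uV).
#' @param stim_response list with `peak_gain` (fractional gain of the
#'   slow-oscillation component at its peak), `peak_latency` (s) and
#'   `decay_tau` (s) of the injected stimulus-evoked response; an optional
#'   `baseline_coupling` scales each window's peak gain by its 5 s pre-ON
#'   slow-oscillation level relative to the mean level (default 0: the
#'   evoked gain is baseline-independent).
#' @param cardiac list with `base_hr` (bpm), `rsa_amp`/`rsa_freq` (ms / Hz
#'   respiratory sinus arrhythmia), `drift_amp`/`drift_freq` (slow drift),
#'   `rr_noise_ms` (white RR jitter), `ihr_kernel` (stimulus-locked RR
#'   kernel: `accel_ms`, `accel_dur_s`, `decel_ms`, `decel_dur_s`) and
#'   `ecg_noise_mv`.
#' @param so_preset "narrowband" (amplitude-modulated 0.5-2 Hz noise,
#'   default) or "sinusoid" (clean sine at `so_freq`, used for phase-locking
#'   validation where analytic phase must be known).
#' @param seed integer; identical seeds give bit-identical recordings.
#' @return a validated list of class `synth_params`.
#' @export
synth_params <- function(sampling_rate = 500,
                         so_freq = 1.0,
                         so_band = c(0.5, 2),
                         so_amp_by_stage = c(WAKE = 0, N1 = 5, N2 = 40,
                                             N3 = 80, REM = 0),
                         delta_amp_by_stage = c(WAKE = 0, N1 = 8, N2 = 20,
                                                N3 = 30, REM = 0),
                         beta_amp_by_stage = c(WAKE = 10, N1 = 3, N2 = 1.5,
                                               N3 = 1.5, REM = 3),
                         spindle_rate = 2,
                         spindle_freq_range = c(11, 15),
                         spindle_dur_range = c(0.5, 1.5),
                         spindle_amp = 25,
                         spindle_amp_jitter = 0.2,
                         noise_exponent = 1,
                         noise_amp = 15,
                         eog_defl_rate = 5,
                         movement_rate = 2,
                         movement_amp = 400,
                         stim_response = list(peak_gain = 0.8,
                                              peak_latency = 0.5,
                                              decay_tau = 3),
                         cardiac = list(base_hr = 60, rsa_amp = 40,
                                        rsa_freq = 0.25, drift_amp = 30,
                                        drift_freq = 0.005, rr_noise_ms = 3,
                                        ihr_kernel = list(accel_ms = 10,
                                                          accel_dur_s = 4,
                                                          decel_ms = 20,
                                                          decel_dur_s = 8),
                                        ecg_noise_mv = 0.02),
                         so_preset = c("narrowband", "sinusoid"),
                         seed = 1L) {
  so_preset <- match.arg(so_preset)
  p <- list(sampling_rate = sampling_rate, so_freq = so_freq,
            so_band = so_band, so_amp_by_stage = so_amp_by_stage,
            delta_amp_by_stage = delta_amp_by_stage,
            beta_amp_by_stage = beta_amp_by_stage,
            spindle_rate = spindle_rate,
            spindle_freq_range = spindle_freq_range,
            spindle_dur_range = spindle_dur_range,
            spindle_amp = spindle_amp,
            spindle_amp_jitter = spindle_amp_jitter,
            noise_exponent = noise_exponent,
            noise_amp = noise_amp, eog_defl_rate = eog_defl_rate,
            movement_rate = movement_rate, movement_amp = movement_amp,
            stim_response = stim_response, cardiac = cardiac,
            so_preset = so_preset, seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  amp_ok <- function(v) all(is.finite(v)) && all(v >= 0)
  stopifnot(p$sampling_rate > 0,
            amp_ok(p$so_amp_by_stage), amp_ok(p$delta_amp_by_stage),
            amp_ok(p$beta_amp_by_stage),
            p$spindle_rate >= 0, p$spindle_amp >= 0, p$noise_amp >= 0,
            p$movement_rate >= 0, p$eog_defl_rate >= 0)
  if (!all(names(p$so_amp_by_stage) %in% STAGES))
    stop("so_amp_by_stage must be named by sleep stage")
  if (p$sampling_rate <= 2 * max(p$spindle_freq_range, 30))
    stop("sampling_rate must exceed twice the highest generated frequency")
  if (p$cardiac$base_hr < 30 || p$cardiac$base_hr > 120)
    stop("base_hr must lie in 30-120 bpm")
  invisible(p)
}

#' Generate a plausible night hypnogram
#'
#' Builds sleep cycles of roughly 90 min descending into N2/N3, with REM
#' periods lengthening across the night, in fixed 20 s epochs.  The first
#' NREM block is always a continuous N2/N3 run of well over 10 min so that
#' downstream stimulation-eligibility logic can engage.
#'
#' @param duration_h night length in hours (> 0).
#' @param seed integer seed.
#' @return a `hypnogram`.
#' @export
generate_hypnogram <- function(duration_h, seed = 1L) {
  if (!is.numeric(duration_h) || duration_h <= 0)
    stop("duration must be positive")
  n_epochs <- round(duration_h * 3600 / EPOCH_SEC)
  with_seed(seed, {
    stages <- character(0)
    jit <- function(n) max(1L, round(n * stats::runif(1, 0.85, 1.15)))
    # sleep-onset latency
    stages <- c(stages, rep("WAKE", jit(9)), rep("N1", jit(4)))
    cycle <- 0L
    while (length(stages) < n_epochs) {
      cycle <- cycle + 1L
      n3 <- jit(max(15, 75 - 18 * (cycle - 1)))     # N3 shrinks over cycles
      rem <- jit(min(75, 12 + 15 * (cycle - 1)))    # REM grows over cycles
      stages <- c(stages,
                  rep("N2", jit(30)), rep("N3", n3), rep("N2", jit(20)),
                  rep("REM", rem), rep("N1", jit(3)))
    }
    hypnogram(stages[seq_len(n_epochs)])
  })
}

# Smooth a per-sample stage amplitude profile with a ~2 s ramp so stage
# transitions do not generate clicks.
smooth_profile <- function(amp, rate, ramp_sec = 2) {
  k <- max(1L, round(ramp_sec * rate))
  cs <- cumsum(c(0, amp))
  n <- length(amp)
  lo <- pmax(seq_len(n) - k, 0)
  (cs[seq_len(n) + 1] - cs[lo + 1]) / (seq_len(n) - lo)
}

#' Generate synthetic EEG and EOG for a hypnogram
#'
#' EEG channels (Fz, Cz) contain a stage-scaled slow-oscillation component
#' (amplitude-modulated 0.5-2 Hz narrowband noise, or a clean sinusoid under
#' the `sinusoid` preset), stage-scaled delta (2-4.5 Hz) and beta (20-30 Hz)
#' activity, Poisson-placed Gaussian-windowed spindles in N2/N3, 1/f
#' background noise and occasional large movement artifacts.  The EOG pair
#' shares slow frontal leakage and carries anti-correlated deflections only
#' during REM.  Everything injected is logged in the returned ground truth.
#'
#' @param hyp a `hypnogram`.
#' @param params a `synth_params`.
#' @param store_so keep the per-channel slow-oscillation component in the
#'   ground truth (needed by [inject_stim_response()] to scale the
#'   oscillation without touching noise).  Default TRUE.
#' @return list with `recording` (a `signal_recording`) and `truth` (ground
#'   truth: spindle/movement/eye-movement event tables, slow-oscillation
#'   component and preset info).
#' @export
generate_eeg <- function(hyp, params, store_so = TRUE) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(params, "synth_params"))
  if (length(hyp$stages) == 0) stop("empty hypnogram")
  fs <- params$sampling_rate
  n <- hyp$duration * fs
  stg <- stage_samples(hyp, fs)
  tt <- (seq_len(n) - 1) / fs

  with_seed(params$seed, {
    so_amp <- smooth_profile(params$so_amp_by_stage[stg], fs)
    delta_amp <- smooth_profile(params$delta_amp_by_stage[stg], fs)
    beta_amp <- smooth_profile(params$beta_amp_by_stage[stg], fs)

    if (params$so_preset == "sinusoid") {
      ph0 <- stats::runif(1, 0, 2 * pi)
      so_base <- sin(2 * pi * params$so_freq * tt + ph0)
      so_info <- list(preset = "sinusoid", freq = params$so_freq,
                      phase0 = ph0)
      so_base <- so_base * sqrt(2)           # unit RMS like the noise route
    } else {
      so_base <- bandpass(stats::rnorm(n), fs, params$so_band, order = 2)
      so_base <- so_base / stats::sd(so_base)
      # infraslow depth-of-sleep amplitude modulation (0.05 Hz, seeded
      # random phase).  Deliberately periodic: its fixed-lag correlations
      # are handled by jittered window spacing in analyses, whereas an
      # aperiodic modulator's 5-50 s correlation times leave slow
      # structured noise in window averages that drowns decay-constant
      # estimation at realistic window counts.
      am <- 1 + 0.3 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi))
      so_base <- so_base * pmax(am, 0.2)
      so_info <- list(preset = "narrowband", freq = NA_real_, phase0 = NA)
    }

    mk_band <- function(band) {
      x <- bandpass(stats::rnorm(n), fs, band, order = 2)
      x / stats::sd(x)
    }

    spikes <- spindle_train(hyp, params, fs, n)
    movements <- movement_train(hyp, params, fs, n)

    channels <- list(Fz = 1.0, Cz = 0.85)
    signals <- list(); so_store <- list()
    for (ch in names(channels)) {
      g <- channels[[ch]]
      so_ch <- so_base * so_amp * g
      x <- so_ch +
        mk_band(c(2, 4.5)) * delta_amp * g +
        mk_band(c(20, 30)) * beta_amp * g +
        pink_noise(n, params$noise_exponent) * params$noise_amp +
        spikes$wave * g + movements$wave
      signals[[ch]] <- x
      if (store_so) so_store[[ch]] <- so_ch
    }

    # EOG pair: band-limited noise + shared frontal leakage; REM adds
    # anti-correlated deflections.
    leak <- 0.2 * so_base * so_amp
    eog1 <- bandpass(stats::rnorm(n), fs, c(0.1, 5), order = 2)
    eog2 <- bandpass(stats::rnorm(n), fs, c(0.1, 5), order = 2)
    eog1 <- eog1 / stats::sd(eog1) * 8 + leak
    eog2 <- eog2 / stats::sd(eog2) * 8 + leak
    defl <- eog_deflections(hyp, params, fs, n)
    signals$EOG1 <- eog1 + defl$wave
    signals$EOG2 <- eog2 - defl$wave

    rec <- signal_recording(
      signals,
      rates = stats::setNames(rep(fs, length(signals)), names(signals)),
      roles = c(Fz = "EEG", Cz = "EEG", EOG1 = "EOG", EOG2 = "EOG"))
    truth <- list(spindles = spikes$events, movements = movements$events,
                  eog_deflections = defl$events, so = so_info,
                  so_component = if (store_so) so_store else NULL,
                  injected_windows = NULL, params = params)
    list(recording = rec, truth = truth)
  })
}

# Poisson spindle placement in N2 (full rate) and N3 (half rate).
# Spindle morphology: Tukey(0.5)-windowed sinusoid.
spindle_train <- function(hyp, params, fs, n) {
  wave <- numeric(n)
  ev <- list()
  if (params$spindle_rate > 0 && params$spindle_amp > 0) {
    for (i in seq_along(hyp$stages)) {
      rate_min <- switch(hyp$stages[i], N2 = params$spindle_rate,
                         N3 = params$spindle_rate / 2, 0)
      if (rate_min == 0) next
      k <- stats::rpois(1, rate_min * EPOCH_SEC / 60)
      if (k == 0) next
      for (j in seq_len(k)) {
        dur <- stats::runif(1, params$spindle_dur_range[1],
                            params$spindle_dur_range[2])
        start <- (i - 1) * EPOCH_SEC + stats::runif(1, 0, EPOCH_SEC - dur)
        freq <- stats::runif(1, params$spindle_freq_range[1],
                             params$spindle_freq_range[2])
        jit <- params$spindle_amp_jitter
        amp <- params$spindle_amp * stats::runif(1, 1 - jit, 1 + jit)
        idx <- seq(floor(start * fs) + 1, min(ceiling((start + dur) * fs), n))
        trel <- (idx - 1) / fs - start
        # waxing-waning Tukey envelope: cosine tapers over the outer halves,
        # sustained core, so the event's nominal duration is the duration of
        # oscillation near peak amplitude
        u <- trel / dur
        envl <- ifelse(u < 0.25, 0.5 * (1 - cos(4 * pi * u)),
                       ifelse(u > 0.75, 0.5 * (1 - cos(4 * pi * (1 - u))), 1))
        wave[idx] <- wave[idx] +
          amp * envl *
          sin(2 * pi * freq * trel + stats::runif(1, 0, 2 * pi))
        ev[[length(ev) + 1]] <- data.frame(start = start, duration = dur,
                                           freq = freq, amp = amp)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start = numeric(0), duration = numeric(0),
               freq = numeric(0), amp = numeric(0))
  list(wave = wave, events = events[order(events$start), , drop = FALSE])
}

movement_train <- function(hyp, params, fs, n) {
  wave <- numeric(n)
  ev <- list()
  if (params$movement_rate > 0) {
    k <- stats::rpois(1, params$movement_rate * hyp$duration / 3600)
    for (j in seq_len(k)) {
      dur <- stats::runif(1, 0.5, 2)
      start <- stats::runif(1, 0, hyp$duration - dur)
      idx <- seq(floor(start * fs) + 1, min(ceiling((start + dur) * fs), n))
      env <- sin(pi * (idx - idx[1]) / length(idx))
      burst <- sin(2 * pi * stats::runif(1, 1, 4) * (idx - 1) / fs +
                     stats::runif(1, 0, 2 * pi))
      wave[idx] <- wave[idx] + params$movement_amp * env * burst
      ev[[length(ev) + 1]] <- data.frame(start = start, duration = dur)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start = numeric(0), duration = numeric(0))
  list(wave = wave, events = events[order(events$start), , drop = FALSE])
}

eog_deflections <- function(hyp, params, fs, n) {
  wave <- numeric(n)
  ev <- list()
  if (params$eog_defl_rate > 0) {
    for (i in seq_along(hyp$stages)) {
      if (hyp$stages[i] != "REM") next
      k <- stats::rpois(1, params$eog_defl_rate * EPOCH_SEC / 60)
      for (j in seq_len(k)) {
        w <- stats::runif(1, 0.5, 1.5)
        start <- (i - 1) * EPOCH_SEC + stats::runif(1, 0, EPOCH_SEC - w)
        amp <- stats::runif(1, 60, 150) * sample(c(-1, 1), 1)
        idx <- seq(floor(start * fs) + 1, min(ceiling((start + w) * fs), n))
        wave[idx] <- wave[idx] + amp * sin(pi * (idx - idx[1]) / length(idx))
        ev[[length(ev) + 1]] <- data.frame(start = start, duration = w,
                                           amp = amp)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start = numeric(0), duration = numeric(0), amp = numeric(0))
  list(wave = wave, events = events)
}

#' Inject a stimulus-evoked slow-wave response into stimulation windows
#'
#' Within each non-SHAM stimulation ON window the slow-oscillation component
#' is multiplied by `1 + g(t)` where `g` ramps linearly from 0 to
#' `peak_gain` over `peak_latency` seconds and then decays exponentially
#' with time constant `decay_tau`.  Only the band-limited slow-oscillation
#' component is scaled; broadband noise is untouched, so recovery tests can
#' compare against the known injected kernel.  SHAM windows and all samples
#' outside ON windows are bit-identical to the input.
#'
#' @param eeg a `signal_recording` from [generate_eeg()].
#' @param windows stimulation-window table (see [stim_windows()]).
#' @param params a `synth_params` (uses `stim_response`).
#' @param truth ground truth from [generate_eeg()]; if it carries the stored
#'   slow-oscillation component that component is scaled, otherwise the
#'   0.5-2 Hz band of the signal itself is used.
#' @return list with modified `recording` and updated `truth` (injected
#'   windows logged).
#' @export
inject_stim_response <- function(eeg, windows, params, truth = NULL) {
  stopifnot(inherits(eeg, "signal_recording"))
  sr <- params$stim_response
  if (nrow(windows) &&
      any(windows$on_start < 0 |
          windows$on_start + windows$on_dur + windows$off_dur >
            eeg$duration + 1e-9))
    stop("stimulation window outside the recording")
  target <- windows[windows$condition != "SHAM", , drop = FALSE]
  coupling <- sr$baseline_coupling
  if (is.null(coupling)) coupling <- 0
  injected <- target
  if (sr$peak_gain == 0 || nrow(target) == 0) {
    if (nrow(injected)) injected$peak_gain <- sr$peak_gain
    if (!is.null(truth)) truth$injected_windows <- injected
    return(list(recording = eeg, truth = truth))
  }
  gains <- rep(sr$peak_gain, nrow(target))
  for (ch in channels_by_role(eeg, "EEG")) {
    fs <- eeg$rates[[ch]]
    so <- if (!is.null(truth$so_component[[ch]])) truth$so_component[[ch]]
          else bandpass(eeg$signals[[ch]], fs, params$so_band, order = 2)
    if (coupling != 0 && ch == channels_by_role(eeg, "EEG")[1]) {
      # per-window peak gain scaled by the 5 s pre-ON slow-oscillation
      # level relative to the across-window mean level
      base <- vapply(seq_len(nrow(target)), function(i) {
        i1 <- floor(target$on_start[i] * fs)
        i0 <- max(i1 - round(5 * fs) + 1, 1)
        sqrt(mean(so[i0:i1]^2))
      }, numeric(1))
      gains <- pmax(sr$peak_gain *
                      (1 + coupling * (base / mean(base) - 1)), 0)
    }
    x <- eeg$signals[[ch]]
    for (i in seq_len(nrow(target))) {
      i0 <- floor(target$on_start[i] * fs) + 1
      i1 <- min(ceiling((target$on_start[i] + target$on_dur[i]) * fs),
                length(x))
      trel <- (seq(i0, i1) - 1) / fs - target$on_start[i]
      g <- ifelse(trel < sr$peak_latency,
                  gains[i] * trel / sr$peak_latency,
                  gains[i] * exp(-(trel - sr$peak_latency) / sr$decay_tau))
      x[i0:i1] <- x[i0:i1] + so[i0:i1] * g
    }
    eeg$signals[[ch]] <- x
  }
  injected$peak_gain <- gains
  if (!is.null(truth)) truth$injected_windows <- injected
  list(recording = eeg, truth = truth)
}

#' Generate an RR-interval series and rendered ECG
#'
#' RR intervals follow `60000 / base_hr` plus respiratory sinus arrhythmia,
#' a slow drift, white jitter and — after every non-SHAM stimulation ON
#' onset — a biphasic kernel: a brief RR shortening (heart-rate
#' acceleration) over the first `accel_dur_s` seconds followed by a longer
#' RR lengthening (deceleration).  An ECG trace with template QRS complexes
#' at the R times is rendered for peak-detection testing.
#'
#' @param duration_s recording length in seconds.
#' @param windows stimulation-window table (may have zero rows).
#' @param params a `synth_params` (uses `cardiac`).
#' @return list with `rr` (an `rr_series`), `ecg` (a one-channel
#'   `signal_recording`) and `truth` (noise-free baseline RR at the same
#'   beat times and the kernel settings).
#' @export
generate_rr <- function(duration_s, windows, params) {
  cd <- params$cardiac
  k <- cd$ihr_kernel
  base_rr <- 60000 / cd$base_hr
  if (base_rr - cd$rsa_amp - cd$drift_amp - k$accel_ms -
        6 * cd$rr_noise_ms <= 0)
    stop("cardiac modulation amplitudes imply non-positive RR intervals")
  stim <- windows[windows$condition != "SHAM", , drop = FALSE]
  on_starts <- sort(stim$on_start)
  kern <- function(t) {
    if (!length(on_starts)) return(0)
    i <- findInterval(t, on_starts)
    if (i == 0) return(0)
    tau <- t - on_starts[i]
    if (tau < k$accel_dur_s)
      -k$accel_ms * sin(pi * tau / k$accel_dur_s)
    else if (tau < k$accel_dur_s + k$decel_dur_s)
      k$decel_ms * sin(pi * (tau - k$accel_dur_s) / k$decel_dur_s)
    else 0
  }
  with_seed(params$seed + 1L, {
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    clean <- function(t)
      base_rr + cd$rsa_amp * sin(2 * pi * cd$rsa_freq * t + ph1) +
        cd$drift_amp * sin(2 * pi * cd$drift_freq * t + ph2) + kern(t)
    t <- 0.5; times <- numeric(0); rr_base <- numeric(0)
    while (TRUE) {
      rr <- clean(t) + stats::rnorm(1, 0, cd$rr_noise_ms)
      times <- c(times, t); rr_base <- c(rr_base, clean(t))
      t <- t + rr / 1000
      if (t >= duration_s) break
      if (length(times) > duration_s * 4) stop("runaway RR generation")
    }
    fs <- params$sampling_rate
    n <- round(duration_s * fs)
    ecg <- stats::rnorm(n, 0, cd$ecg_noise_mv)
    tpl <- qrs_template(fs)
    half <- (length(tpl$wave) - 1) / 2
    for (rt in times) {
      c0 <- round(rt * fs) + 1
      idx <- (c0 - half):(c0 + half)
      keep <- idx >= 1 & idx <= n
      ecg[idx[keep]] <- ecg[idx[keep]] + tpl$wave[keep]
    }
    rr <- rr_series(times)
    rec <- signal_recording(list(ECG = ecg), rates = c(ECG = fs),
                            roles = c(ECG = "ECG"))
    list(rr = rr, ecg = rec,
         truth = list(r_times = times, rr_baseline = rr_base, kernel = k))
  })
}

# Template QRS-T complex sampled at `fs`, ~0.6 s support, R peak centred.
qrs_template <- function(fs) {
  t <- seq(-0.3, 0.3, by = 1 / fs)
  wave <- 1.0 * exp(-(t / 0.012)^2) -
    0.15 * exp(-((t + 0.028) / 0.010)^2) -
    0.20 * exp(-((t - 0.028) / 0.010)^2) +
    0.25 * exp(-((t - 0.18) / 0.06)^2)
  list(t = t, wave = wave)
}
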