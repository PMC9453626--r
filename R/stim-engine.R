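# Offline re-implementation of the closed-loop stimulation algorithm:
# causal band-power streams, sleep-state gating with beta/EOG/movement/delta
# gates, a first-order phase-locked loop for slow-oscillation phase
# targeting, ON/OFF window scheduling and per-condition tone planning.
#
# Everything here is causal: outputs at time t use samples at or before t.

#' Configuration of the online sleep detector and PLL
#'
#' @param bands list of detection bands (Hz): `low_delta` 2-4,
#'   `high_delta` 3-5, `high_beta` 20-30.
#' @param first_stable_nrem s of uninterrupted detected NREM required before
#'   the first stimulation (default 600 = 10 min).
#' @param later_stable_nrem s required after an interruption (default 180).
#' @param movement_holdoff s stimulation is delayed after a movement.
#' @param power_window s of the sliding band-power window.
#' @param update_step s between detector updates.
#' @param beta_k SD multiplier of the beta-power threshold
#'   (threshold = mean + beta_k * SD of the calibration segment).
#' @param eog_anticorr_cut gate closes while the sliding EOG correlation is
#'   below this (default -0.6).
#' @param eog_window s of the sliding EOG correlation window.
#' @param movement_amp_cut uV; absolute EEG amplitude marking a movement.
#' @param delta_gate_quantile stimulate only while low-delta power exceeds
#'   this quantile of the calibration segment (default 0.25).
#' @param nrem_ratio_cut low-delta / high-beta power ratio above which the
#'   detector calls NREM.
#' @param so_band slow-oscillation band fed to the PLL.
#' @param pll_rate Hz; the PLL runs on the causally filtered slow-wave
#'   signal decimated to this rate.
#' @param pll list of PLL internals: `loop_gain` (rad/s of phase correction
#'   per unit detector output), `err_lp_hz` (one-pole smoothing of the
#'   phase-detector output), `agc_tau` (s, amplitude-normalisation time
#'   constant), `lock_err_deg` (smoothed phase error below which the loop
#'   counts as locked), `lock_time` (s the error must stay small),
#'   `amp_min` (uV, minimum tracked amplitude for lock).
#' @param stim_channel EEG channel the engine runs on (default: first EEG).
#' @return a `detector_config`.
#' @export
detector_config <- function(bands = list(low_delta = c(2, 4),
                                         high_delta = c(3, 5),
                                         high_beta = c(20, 30)),
                            first_stable_nrem = 600,
                            later_stable_nrem = 180,
                            movement_holdoff = 10,
                            power_window = 2,
                            update_step = 0.5,
                            beta_k = 2,
                            eog_anticorr_cut = -0.6,
                            eog_window = 4,
                            movement_amp_cut = 300,
                            delta_gate_quantile = 0.25,
                            nrem_ratio_cut = 3,
                            so_band = c(0.5, 2),
                            pll_rate = 100,
                            pll = list(loop_gain = 6, err_lp_hz = 0.8,
                                       agc_tau = 3, lock_err_deg = 30,
                                       lock_time = 2, amp_min = 5),
                            stim_channel = NULL) {
  stopifnot(first_stable_nrem > later_stable_nrem,
            update_step > 0, update_step <= power_window,
            all(vapply(bands, function(b) b[1] < b[2], logical(1))))
  structure(list(bands = bands, first_stable_nrem = first_stable_nrem,
                 later_stable_nrem = later_stable_nrem,
                 movement_holdoff = movement_holdoff,
                 power_window = power_window, update_step = update_step,
                 beta_k = beta_k, eog_anticorr_cut = eog_anticorr_cut,
                 eog_window = eog_window,
                 movement_amp_cut = movement_amp_cut,
                 delta_gate_quantile = delta_gate_quantile,
                 nrem_ratio_cut = nrem_ratio_cut, so_band = so_band,
                 pll_rate = pll_rate, pll = pll,
                 stim_channel = stim_channel),
            class = "detector_config")
}

# Step-grid times for a signal of n samples at `rate`: k * update_step for
# k = 1.. while the full step lies inside the recording.
step_times <- function(n, rate, cfg) {
  dur <- n / rate
  seq(cfg$update_step, dur + 1e-9, by = cfg$update_step)
}

#' Causal sliding-window band power
#'
#' Forward-only (causal) Butterworth band-pass followed by a running mean of
#' the squared signal over `power_window` seconds, sampled every
#' `update_step`.  Power at time t uses samples in (t - power_window, t].
#'
#' @param x numeric EEG vector.
#' @param rate sampling rate (Hz).
#' @param band length-2 band edges (Hz), below Nyquist.
#' @param cfg a `detector_config`.
#' @return data.frame with `time` (s, window end) and `power`.
#' @export
band_power_stream <- function(x, rate, band, cfg = detector_config()) {
  if (band[2] >= rate / 2) stop("band above Nyquist")
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  y <- as.numeric(signal::filter(bf, x))          # causal, single pass
  p <- y^2
  w <- round(cfg$power_window * rate)
  cs <- c(0, cumsum(p))
  ts <- step_times(length(x), rate, cfg)
  idx <- pmin(round(ts * rate), length(x))
  lo <- pmax(idx - w, 0)
  data.frame(time = ts, power = (cs[idx + 1] - cs[lo + 1]) / (idx - lo))
}

#' Beta-power threshold from the calibration segment
#'
#' The first 10 min of detected NREM serve to calibrate a beta-power
#' threshold; stimulation halts whenever beta power later exceeds it.
#'
#' @param beta numeric vector of beta-power samples from the calibration
#'   segment.
#' @param beta_k SD multiplier.
#' @return threshold = mean + beta_k * SD (sample SD; 0 for length-1 input).
#' @export
calibrate_beta_threshold <- function(beta, beta_k = 2) {
  if (!length(beta)) stop("no calibration samples: calibration pending")
  s <- if (length(beta) > 1) stats::sd(beta) else 0
  mean(beta) + beta_k * s
}

#' EOG anti-correlation gate
#'
#' Sliding Pearson correlation between the two EOG derivations over
#' `eog_window` seconds; the gate closes (REM-like eye movements) while the
#' correlation is below `eog_anticorr_cut`.  Zero-variance segments yield a
#' correlation of 0 (gate open).
#'
#' @param eog1,eog2 equal-length EOG vectors.
#' @param rate sampling rate (Hz).
#' @param cfg a `detector_config`.
#' @return data.frame with `time`, `r`, `open`.
#' @export
eog_anticorr_gate <- function(eog1, eog2, rate, cfg = detector_config()) {
  stopifnot(length(eog1) == length(eog2))
  w <- round(cfg$eog_window * rate)
  cs1 <- c(0, cumsum(eog1)); cs2 <- c(0, cumsum(eog2))
  cs11 <- c(0, cumsum(eog1^2)); cs22 <- c(0, cumsum(eog2^2))
  cs12 <- c(0, cumsum(eog1 * eog2))
  ts <- step_times(length(eog1), rate, cfg)
  idx <- pmin(round(ts * rate), length(eog1))
  lo <- pmax(idx - w, 0)
  n <- idx - lo
  s1 <- cs1[idx + 1] - cs1[lo + 1]; s2 <- cs2[idx + 1] - cs2[lo + 1]
  s11 <- cs11[idx + 1] - cs11[lo + 1]; s22 <- cs22[idx + 1] - cs22[lo + 1]
  s12 <- cs12[idx + 1] - cs12[lo + 1]
  v1 <- s11 - s1^2 / n; v2 <- s22 - s2^2 / n
  r <- ifelse(v1 <= 1e-12 | v2 <= 1e-12, 0,
              (s12 - s1 * s2 / n) / sqrt(pmax(v1, 0) * pmax(v2, 0)))
  data.frame(time = ts, r = r, open = r >= cfg$eog_anticorr_cut)
}

#' Movement gate
#'
#' The gate closes whenever the absolute EEG amplitude exceeds
#' `movement_amp_cut` and stays closed for `movement_holdoff` seconds after
#' the last exceeding sample.
#'
#' @param x numeric EEG vector.
#' @param rate sampling rate (Hz).
#' @param cfg a `detector_config`.
#' @return data.frame with `time`, `open`.
#' @export
movement_gate <- function(x, rate, cfg = detector_config()) {
  exceed <- abs(x) > cfg$movement_amp_cut
  cs <- c(0, cumsum(exceed))
  ts <- step_times(length(x), rate, cfg)
  idx <- pmin(round(ts * rate), length(x))
  lo <- pmax(idx - round(cfg$movement_holdoff * rate), 0)
  recent <- (cs[idx + 1] - cs[lo + 1]) > 0
  data.frame(time = ts, open = !recent)
}

#' NREM stimulation-eligibility state machine
#'
#' Hypnogram-free online logic: NREM is detected where the low-delta /
#' high-beta power ratio exceeds `nrem_ratio_cut` and the EOG gate is open.
#' The first 10 min of uninterrupted detected NREM calibrate the beta-power
#' threshold and the delta (slow-wave sleep) gate; eligibility then requires
#' the stable-NREM counter (10 min for the first episode, 3 min after any
#' interruption), the movement gate open, beta power below threshold and
#' low-delta power above its calibration quantile.
#'
#' @param low_delta,high_beta data.frames from [band_power_stream()] on a
#'   common step grid.
#' @param eog_open,move_open logical vectors on the same grid (default all
#'   open).
#' @param cfg a `detector_config`.
#' @return list with `steps` (data.frame: time, nrem, stable_s, eligible),
#'   `beta_threshold`, `delta_cut`, `calibrated_at` (s or NA).
#' @export
nrem_state_machine <- function(low_delta, high_beta,
                               eog_open = NULL, move_open = NULL,
                               cfg = detector_config()) {
  ts <- low_delta$time
  m <- length(ts)
  stopifnot(nrow(high_beta) == m)
  if (is.null(eog_open)) eog_open <- rep(TRUE, m)
  if (is.null(move_open)) move_open <- rep(TRUE, m)
  dt <- cfg$update_step
  ratio <- low_delta$power / pmax(high_beta$power, 1e-12)
  nrem <- ratio > cfg$nrem_ratio_cut & eog_open

  stable <- numeric(m); eligible <- logical(m)
  beta_thr <- NA_real_; delta_cut <- NA_real_; calibrated_at <- NA_real_
  cal_beta <- numeric(0); cal_delta <- numeric(0)
  s <- 0; had_first <- FALSE
  for (i in seq_len(m)) {
    if (nrem[i]) s <- s + dt else s <- 0
    stable[i] <- s
    if (is.na(beta_thr)) {
      if (nrem[i]) {
        cal_beta <- c(cal_beta, high_beta$power[i])
        cal_delta <- c(cal_delta, low_delta$power[i])
      } else {
        cal_beta <- numeric(0); cal_delta <- numeric(0)
      }
      if (s >= cfg$first_stable_nrem) {
        beta_thr <- calibrate_beta_threshold(cal_beta, cfg$beta_k)
        delta_cut <- stats::quantile(cal_delta, cfg$delta_gate_quantile,
                                     names = FALSE)
        calibrated_at <- ts[i]
      }
    }
    need <- if (had_first) cfg$later_stable_nrem else cfg$first_stable_nrem
    ok <- !is.na(beta_thr) && s >= need && move_open[i] &&
      high_beta$power[i] <= beta_thr && low_delta$power[i] >= delta_cut
    if (ok) had_first <- TRUE
    eligible[i] <- ok
  }
  list(steps = data.frame(time = ts, nrem = nrem, stable_s = stable,
                          eligible = eligible),
       beta_threshold = beta_thr, delta_cut = delta_cut,
       calibrated_at = calibrated_at)
}

# ---------------------------------------------------------------------------
# First-order phase-locked loop

#' Initialise PLL state
#'
#' @param cfg a `detector_config` (uses `$pll` and `$so_band`).
#' @param center_freq Hz, free-running frequency (default 1).
#' @return a `pll_state` list.
#' @export
pll_init <- function(cfg = detector_config(), center_freq = 1.0) {
  structure(list(center_freq = center_freq, theta = 0, err = 0,
                 ms = 0, lock_m = 1, lock_timer = 0, locked = FALSE,
                 cfg = cfg$pll), class = "pll_state")
}

#' Advance the PLL by one sample
#'
#' The phase detector multiplies the amplitude-normalised input by the
#' quadrature reference `cos(theta)`; for input `A sin(phi)` this gives
#' `sin(phi - theta)/2` after low-pass smoothing, so `theta` tracks the
#' sine-convention phase of the slow oscillation.  The estimate advances at
#' the centre frequency corrected by `loop_gain` times the smoothed error
#' (first-order loop).  Lock requires the smoothed error to stay below
#' `lock_err_deg` for `lock_time` seconds with sufficient tracked amplitude.
#'
#' @param sample one value of the causally band-limited slow-wave signal.
#' @param state a `pll_state`.
#' @param dt sample interval in seconds.
#' @return updated `pll_state`; `$theta` is the phase estimate in radians
#'   (unwrapped, sine convention), `$locked` the lock flag.
#' @export
pll_step <- function(sample, state, dt) {
  p <- state$cfg
  aa <- dt / p$agc_tau
  state$ms <- (1 - aa) * state$ms + aa * sample^2
  amp <- sqrt(2 * max(state$ms, 0))
  xn <- if (amp > p$amp_min / 10) sample / amp else 0
  e_raw <- xn * cos(state$theta)
  ae <- 1 - exp(-2 * pi * p$err_lp_hz * dt)
  state$err <- state$err + ae * (e_raw - state$err)
  state$theta <- state$theta + 2 * pi * state$center_freq * dt +
    p$loop_gain * state$err * dt
  # lock metric: slowly smoothed signed error (err ~ sin(delta)/2 for unit
  # input); smoothing the signed value cancels double-frequency ripple
  al <- dt / 1.0
  state$lock_m <- state$lock_m + al * (state$err - state$lock_m)
  small <- abs(state$lock_m) < sin(p$lock_err_deg * pi / 180) / 2
  has_amp <- amp >= p$amp_min
  state$lock_timer <- if (small && has_amp) state$lock_timer + dt else 0
  state$locked <- state$lock_timer >= p$lock_time
  state
}

#' Run the PLL over a slow-wave signal
#'
#' @param x causally band-limited slow-wave signal (see
#'   [causal_slow_wave()]).
#' @param rate sampling rate of `x` (Hz).
#' @param cfg a `detector_config`.
#' @param center_freq Hz.
#' @return list with per-sample `theta` (rad, unwrapped), `locked`, `err`.
#' @export
pll_run <- function(x, rate, cfg = detector_config(), center_freq = 1.0) {
  p <- cfg$pll
  dt <- 1 / rate
  n <- length(x)
  theta <- numeric(n); locked <- logical(n); err_v <- numeric(n)
  th <- 0; err <- 0; ms <- 0; lt <- 0; lm <- 1
  aa <- dt / p$agc_tau
  ae <- 1 - exp(-2 * pi * p$err_lp_hz * dt)
  al <- dt / 1.0
  wc <- 2 * pi * center_freq * dt
  small_thr <- sin(p$lock_err_deg * pi / 180) / 2
  amp_floor <- p$amp_min / 10
  for (i in seq_len(n)) {
    xi <- x[i]
    ms <- (1 - aa) * ms + aa * xi * xi
    amp <- sqrt(2 * ms)
    xn <- if (amp > amp_floor) xi / amp else 0
    err <- err + ae * (xn * cos(th) - err)
    th <- th + wc + p$loop_gain * err * dt
    lm <- lm + al * (err - lm)
    lt <- if (abs(lm) < small_thr && amp >= p$amp_min) lt + dt else 0
    theta[i] <- th; err_v[i] <- err; locked[i] <- lt >= p$lock_time
  }
  list(theta = theta, locked = locked, err = err_v, rate = rate)
}

#' Causally filtered, decimated slow-wave signal for the PLL
#'
#' Forward-only Butterworth band-pass in the slow-oscillation band (which
#' has zero phase response at the band's geometric centre, 1 Hz for
#' 0.5-2 Hz), decimated to `pll_rate`.
#'
#' @param x raw EEG vector.
#' @param rate sampling rate (Hz).
#' @param cfg a `detector_config`.
#' @return list with `x` (filtered, decimated), `rate`.
#' @export
causal_slow_wave <- function(x, rate, cfg = detector_config()) {
  bf <- signal::butter(2, cfg$so_band / (rate / 2), type = "pass")
  y <- as.numeric(signal::filter(bf, x))
  dec <- max(1L, round(rate / cfg$pll_rate))
  list(x = y[seq(1, length(y), by = dec)], rate = rate / dec)
}

#' Target-phase trigger times from a PLL run
#'
#' A trigger fires each time the unwrapped phase estimate crosses
#' `target_deg` (mod 360) while the loop is locked.
#'
#' @param pll output of [pll_run()].
#' @param target_deg target phase in degrees (sine convention).
#' @return numeric vector of trigger times (s).
#' @export
phase_triggers <- function(pll, target_deg) {
  targ <- target_deg * pi / 180
  k <- floor((pll$theta - targ) / (2 * pi))
  cross <- c(FALSE, diff(k) > 0)
  idx <- which(cross & pll$locked)
  if (!length(idx)) return(numeric(0))
  # linear interpolation of the crossing instant between samples
  th_hit <- (k[idx] ) * 2 * pi + targ
  frac <- (pll$theta[idx] - th_hit) /
    pmax(pll$theta[idx] - pll$theta[idx - 1], 1e-12)
  (idx - 1 - pmin(pmax(frac, 0), 1)) / pll$rate
}

# ---------------------------------------------------------------------------
# Scheduling and tone planning

#' Schedule stimulation windows
#'
#' Walks the night in time: whenever the detector is eligible and a trigger
#' at the upcoming condition's target phase fires, a 10 s ON + 10 s OFF
#' window opens with the next condition from the pseudorandomized sequencer;
#' no new window can start before the OFF window ends.  SHAM windows are
#' scheduled identically but carry no tones.
#'
#' @param eligibility data.frame (`time`, `eligible`) from
#'   [nrem_state_machine()] steps.
#' @param triggers named list of trigger-time vectors per target phase
#'   (names = degrees as character, e.g. `"50"`, `"230"`).
#' @param sequencer a function from [sequence_conditions()].
#' @param conditions named list of `condition_spec`s.
#' @param duration recording duration (s).
#' @param on_dur,off_dur window durations (s).
#' @return a `stim_windows` data.frame (possibly empty).
#' @export
schedule_windows <- function(eligibility, triggers, sequencer, conditions,
                             duration, on_dur = 10, off_dur = 10) {
  step <- if (nrow(eligibility) > 1)
    eligibility$time[2] - eligibility$time[1] else 0.5
  is_eligible <- function(t) {
    i <- findInterval(t, eligibility$time - step + 1e-9)
    i >= 1 && i <= nrow(eligibility) && eligibility$eligible[i]
  }
  out_cond <- character(0); out_start <- numeric(0)
  t_free <- 0
  repeat {
    nxt <- sequencer(peek = TRUE)
    spec <- conditions[[nxt]]
    targ <- if (is.finite(spec$phase_target)) spec$phase_target else 50
    trig <- triggers[[as.character(targ)]]
    cand <- trig[trig >= t_free & trig + on_dur + off_dur <= duration]
    cand <- cand[vapply(cand, is_eligible, logical(1))]
    if (!length(cand)) break
    sequencer()                                  # consume
    out_cond <- c(out_cond, nxt)
    out_start <- c(out_start, cand[1])
    t_free <- cand[1] + on_dur + off_dur
  }
  stim_windows(out_cond, out_start, on_dur = on_dur, off_dur = off_dur)
}

#' Plan the tones of one stimulation window
#'
#' ISI1 variants place tones at 1 s spacing from the ON onset with the
#' condition's volume plan; UP/DOWN place one 50 ms burst per target-phase
#' trigger during ON; ENVELOPE and BINAURAL_BEATS are single 10 s events;
#' SHAM is empty.  A tone whose burst would cross the ON boundary is
#' dropped, keeping the OFF window stimulus-free.
#'
#' @param window one row of a `stim_windows` table.
#' @param condition the matching `condition_spec`.
#' @param triggers trigger times (s, absolute) for the condition's target
#'   phase (UP/DOWN only).
#' @return data.frame with `window_id`, `time` (s), `duration_ms`,
#'   `volume_db` (zero rows for SHAM).
#' @export
plan_tones <- function(window, condition, triggers = numeric(0)) {
  on0 <- window$on_start
  on1 <- on0 + window$on_dur
  empty <- data.frame(window_id = integer(0), time = numeric(0),
                      duration_ms = numeric(0), volume_db = numeric(0))
  if (condition$name == "SHAM") return(empty)
  if (condition$name %in% c("UP", "DOWN")) {
    tt <- triggers[triggers >= on0 & triggers < on1]
    tt <- tt[tt + condition$tone_ms / 1000 <= on1]
    if (!length(tt)) return(empty)
    vol <- rep_len(condition$volume_db, length(tt))
    return(data.frame(window_id = window$window_id, time = tt,
                      duration_ms = condition$tone_ms, volume_db = vol))
  }
  if (condition$name %in% c("ISI1_High", "ISI1_Low", "ISI1_Mod")) {
    k <- length(condition$volume_db)
    tt <- on0 + seq(0, k - 1)
    keep <- tt + condition$tone_ms / 1000 <= on1
    return(data.frame(window_id = window$window_id, time = tt[keep],
                      duration_ms = condition$tone_ms,
                      volume_db = condition$volume_db[keep]))
  }
  # ENVELOPE / BINAURAL_BEATS: one continuous 10 s event
  data.frame(window_id = window$window_id, time = on0,
             duration_ms = min(condition$tone_ms, window$on_dur * 1000),
             volume_db = condition$volume_db[1])
}

#' Render the audio of a stimulation window
#'
#' Pink-noise bursts (1/f spectral shaping, about -3 dB per octave),
#' 1 Hz amplitude-modulated pink noise for ENVELOPE, and dichotic pure
#' tones at carrier / carrier + beat for BINAURAL_BEATS.  Volume in dB maps
#' to relative amplitude with 45 dB as the reference amplitude 1.
#'
#' @param tones tone table from [plan_tones()] (times relative to the
#'   returned waveform start = the window's ON onset).
#' @param condition the `condition_spec`.
#' @param audio_rate audio sampling rate, >= 8000 Hz.
#' @param duration_s waveform length (default 10 s ON window).
#' @param seed seed for the noise synthesis.
#' @return numeric matrix `n x 2` (left, right), silent where no tone plays.
#' @export
render_audio <- function(tones, condition, audio_rate = 16000,
                         duration_s = 10, seed = 1L) {
  stopifnot(audio_rate >= 8000)
  n <- round(duration_s * audio_rate)
  out <- matrix(0, n, 2)
  if (!nrow(tones)) return(out)
  t0 <- min(tones$time)
  with_seed(seed, {
    for (i in seq_len(nrow(tones))) {
      amp <- 10^((tones$volume_db[i] - 45) / 20)
      i0 <- round((tones$time[i] - t0) * audio_rate) + 1
      len <- round(tones$duration_ms[i] / 1000 * audio_rate)
      idx <- i0:(min(i0 + len - 1, n))
      if (condition$name == "BINAURAL_BEATS") {
        tt <- (idx - i0) / audio_rate
        out[idx, 1] <- amp * sin(2 * pi * condition$carrier_hz * tt)
        out[idx, 2] <- amp * sin(2 * pi * (condition$carrier_hz +
                                             condition$beat_hz) * tt)
      } else {
        burst <- pink_noise(length(idx), alpha = 1) * amp
        if (condition$name == "ENVELOPE") {
          tt <- (idx - i0) / audio_rate
          burst <- burst * 0.5 * (1 - cos(2 * pi * 1 * tt))
        }
        out[idx, 1] <- out[idx, 1] + burst
        out[idx, 2] <- out[idx, 2] + burst
      }
    }
  })
  out
}

#' Run the full closed-loop engine on a recording
#'
#' Computes the causal power streams and gates, runs the eligibility state
#' machine and the PLL, schedules pseudorandomized ON/OFF windows and plans
#' each window's tones.
#'
#' @param rec a `signal_recording` with at least one EEG channel (EOG pair
#'   optional).
#' @param cfg a `detector_config`.
#' @param conditions named list of `condition_spec`s
#'   (default [default_conditions()]).
#' @param seed sequencer seed.
#' @return list with `windows` (`stim_windows`), `tones` (data.frame),
#'   `state` (state-machine output), `pll` (PLL run), `triggers` (list per
#'   target), `cfg`.
#' @export
run_stim_engine <- function(rec, cfg = detector_config(),
                            conditions = default_conditions(), seed = 1L) {
  ch <- cfg$stim_channel
  if (is.null(ch)) ch <- channels_by_role(rec, "EEG")[1]
  if (is.na(ch)) stop("recording has no EEG channel")
  x <- rec$signals[[ch]]
  fs <- rec$rates[[ch]]

  low_delta <- band_power_stream(x, fs, cfg$bands$low_delta, cfg)
  high_beta <- band_power_stream(x, fs, cfg$bands$high_beta, cfg)
  mov <- movement_gate(x, fs, cfg)
  eogs <- channels_by_role(rec, "EOG")
  eog_open <- if (length(eogs) >= 2)
    eog_anticorr_gate(rec$signals[[eogs[1]]], rec$signals[[eogs[2]]],
                      rec$rates[[eogs[1]]], cfg)$open
  else rep(TRUE, nrow(low_delta))
  m <- nrow(low_delta)
  state <- nrem_state_machine(low_delta, high_beta,
                              eog_open = eog_open[seq_len(m)],
                              move_open = mov$open[seq_len(m)], cfg)

  sw <- causal_slow_wave(x, fs, cfg)
  pll <- pll_run(sw$x, sw$rate, cfg)
  targets <- unique(stats::na.omit(vapply(conditions,
                                          function(c) c$phase_target,
                                          numeric(1))))
  if (!50 %in% targets) targets <- c(targets, 50)
  triggers <- lapply(stats::setNames(targets, as.character(targets)),
                     function(tg) phase_triggers(pll, tg))

  seqr <- sequence_conditions(names(conditions), seed = seed)
  windows <- schedule_windows(state$steps, triggers, seqr, conditions,
                              duration = rec$duration)
  tone_list <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    spec <- conditions[[w$condition]]
    targ <- if (is.finite(spec$phase_target)) spec$phase_target else 50
    plan_tones(w, spec, triggers[[as.character(targ)]])
  })
  tones <- if (length(tone_list)) do.call(rbind, tone_list) else
    data.frame(window_id = integer(0), time = numeric(0),
               duration_ms = numeric(0), volume_db = numeric(0))
  list(windows = windows, tones = tones, state = state, pll = pll,
       triggers = triggers, cfg = cfg, channel = ch)
}

#' Measure delivered-stimulus phases on a slow-wave signal
#'
#' Runs the causal slow-wave filter, the PLL and the trigger generator at
#' `target_deg`, then measures each trigger's true phase by the zero-phase
#' Hilbert convention (signal proportional to `sin(phase)`) on the 0.5-2 Hz
#' band of the raw signal.
#'
#' @param x raw EEG vector containing a slow oscillation.
#' @param rate sampling rate (Hz).
#' @param target_deg PLL target phase in degrees (50 = up-phase, 230 =
#'   down-phase).
#' @param cfg a `detector_config`.
#' @return list with `phases` (degrees at each delivered trigger),
#'   `trigger_times` (s), `circ_mean`, `circ_sd`, `n`.
#' @export
pll_delivery_phases <- function(x, rate, target_deg,
                                cfg = detector_config()) {
  sw <- causal_slow_wave(x, rate, cfg)
  pll <- pll_run(sw$x, sw$rate, cfg)
  tr <- phase_triggers(pll, target_deg)
  ph <- instantaneous_phase(bandpass(x, rate, cfg$so_band))
  idx <- round(tr * rate) + 1
  idx <- idx[idx >= 1 & idx <= length(ph)]
  phases <- ph[idx]
  cs <- if (length(phases)) circular_stats(phases) else
    list(mean_deg = NA_real_, R = 0)
  list(phases = phases, trigger_times = tr, circ_mean = cs$mean_deg,
       circ_sd = if (length(phases)) circular_sd(phases) else NA_real_,
       n = length(phases))
}
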