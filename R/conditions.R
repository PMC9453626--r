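# Auditory stimulation conditions and the stimulation-window table.

#' Specification of one auditory stimulation condition
#'
#' @param name condition label; one of UP, DOWN, ISI1_High, ISI1_Low,
#'   ISI1_Mod, ENVELOPE, BINAURAL_BEATS, SHAM.
#' @param tone_ms tone (burst) duration in milliseconds.
#' @param volume_db volume plan in dB: a constant, or for ISI1 variants a
#'   vector of one entry per tone.
#' @param carrier_hz carrier frequency (binaural beats only).
#' @param beat_hz beat frequency (binaural beats only).
#' @param phase_target target slow-oscillation phase in degrees (sine
#'   convention), or NA for conditions that are not phase-locked per tone.
#' @return a `condition_spec`.
#' @export
condition_spec <- function(name, tone_ms = 50, volume_db = 45,
                           carrier_hz = NA_real_, beat_hz = NA_real_,
                           phase_target = NA_real_) {
  name <- match.arg(name, CONDITION_NAMES)
  if (name == "SHAM" && length(volume_db))
    volume_db <- numeric(0)             # SHAM carries no tone plan
  if (name == "ISI1_Mod" && length(volume_db) != 10)
    stop("ISI1_Mod volume plan must have exactly 10 entries")
  structure(list(name = name, tone_ms = tone_ms, volume_db = volume_db,
                 carrier_hz = carrier_hz, beat_hz = beat_hz,
                 phase_target = phase_target),
            class = "condition_spec")
}

CONDITION_NAMES <- c("UP", "DOWN", "ISI1_High", "ISI1_Low", "ISI1_Mod",
                     "ENVELOPE", "BINAURAL_BEATS", "SHAM")

#' Default condition roster
#'
#' Returns the standard condition set: phase-targeted UP (50 deg) and DOWN
#' (230 deg) 50 ms pink-noise bursts, rhythmic 1 Hz trains at constant 45 dB
#' (ISI1_High), constant 42.5 dB (ISI1_Low) or with the ramped volume plan
#' 40, 40, 42.5, 42.5, 45, 45, 45, 45, 42.5, 42.5 dB (ISI1_Mod), 10 s
#' amplitude-modulated pink noise (ENVELOPE), 400/401 Hz binaural beats, and
#' a silent SHAM.
#'
#' @param names subset of condition names to include, in roster order.
#' @return named list of `condition_spec`s.
#' @export
default_conditions <- function(names = c("UP", "DOWN", "ISI1_High",
                                         "ENVELOPE", "BINAURAL_BEATS",
                                         "SHAM")) {
  all <- list(
    UP = condition_spec("UP", tone_ms = 50, volume_db = 45,
                        phase_target = 50),
    DOWN = condition_spec("DOWN", tone_ms = 50, volume_db = 45,
                          phase_target = 230),
    ISI1_High = condition_spec("ISI1_High", tone_ms = 50,
                               volume_db = rep(45, 10), phase_target = 50),
    ISI1_Low = condition_spec("ISI1_Low", tone_ms = 50,
                              volume_db = rep(42.5, 10), phase_target = 50),
    ISI1_Mod = condition_spec("ISI1_Mod", tone_ms = 50,
                              volume_db = c(40, 40, 42.5, 42.5, 45, 45, 45,
                                            45, 42.5, 42.5),
                              phase_target = 50),
    ENVELOPE = condition_spec("ENVELOPE", tone_ms = 10000, volume_db = 45,
                              phase_target = 50),
    BINAURAL_BEATS = condition_spec("BINAURAL_BEATS", tone_ms = 10000,
                                    volume_db = 45, carrier_hz = 400,
                                    beat_hz = 1, phase_target = 50),
    SHAM = condition_spec("SHAM"))
  miss <- setdiff(names, names(all))
  if (length(miss)) stop("unknown conditions: ", paste(miss, collapse = ", "))
  all[names]
}

#' Pseudorandomized condition sequencer
#'
#' Conditions are shuffled once, presented exhaustively, and only then
#' reshuffled — so every block of length `k` contains each condition exactly
#' once and per-condition counts over any run differ by at most one.
#'
#' @param conditions character vector (or list of `condition_spec`) of
#'   conditions to cycle through; at least one.
#' @param seed integer seed; fixed seed gives an identical sequence.
#' @return a function `next_condition()` returning the next condition name;
#'   it also accepts `next_condition(peek = TRUE)` to inspect without
#'   consuming.
#' @export
sequence_conditions <- function(conditions, seed = 1L) {
  if (is.list(conditions))
    conditions <- vapply(conditions, function(c) c$name, character(1))
  if (length(conditions) < 1) stop("need at least one condition")
  rng <- new.env(parent = emptyenv())
  rng$block <- character(0)
  rng$i <- 0L
  rng$draw <- 0L
  refill <- function() {
    rng$draw <- rng$draw + 1L
    rng$block <- with_seed(seed + rng$draw * 10007L,
                           sample(conditions, length(conditions)))
    rng$i <- 0L
  }
  function(peek = FALSE) {
    if (rng$i >= length(rng$block)) refill()
    nxt <- rng$block[rng$i + 1L]
    if (!peek) rng$i <- rng$i + 1L
    nxt
  }
}

#' Construct a stimulation-window table
#'
#' One row per 10 s ON + 10 s OFF stimulation window.  All times in seconds
#' from recording start, half-open intervals.
#'
#' @param condition character vector of condition names.
#' @param on_start numeric vector of ON-window onsets (s).
#' @param on_dur,off_dur window durations (s), default 10 + 10.
#' @param valid logical; artifact/arousal-free N2/N3 flag.
#' @return data.frame with class `stim_windows`.
#' @export
stim_windows <- function(condition, on_start, on_dur = 10, off_dur = 10,
                         valid = TRUE) {
  n <- length(on_start)
  w <- data.frame(window_id = seq_len(n),
                  condition = rep_len(as.character(condition), n),
                  on_start = as.numeric(on_start),
                  on_dur = rep_len(on_dur, n),
                  off_dur = rep_len(off_dur, n),
                  valid = rep_len(valid, n))
  if (n > 1) {
    o <- order(w$on_start)
    ends <- w$on_start[o] + w$on_dur[o] + w$off_dur[o]
    if (any(w$on_start[o][-1] < ends[-n] - 1e-9))
      stop("stimulation windows overlap")
  }
  class(w) <- c("stim_windows", "data.frame")
  w
}
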