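# Containers: SignalRecording (multichannel time series with roles) and
# Hypnogram (20 s staged epochs).

STAGES <- c("WAKE", "N1", "N2", "N3", "REM")
EPOCH_SEC <- 20

#' Construct a multichannel signal recording
#'
#' Channels may have different sampling rates (as EDF allows); each channel
#' carries a role used by the pipeline to find EEG, EOG and ECG traces.
#'
#' @param signals named list of numeric vectors.
#' @param rates named numeric vector of sampling rates (Hz), one per channel.
#' @param roles named character vector, one of "EEG", "EOG", "ECG" per
#'   channel.
#' @param units named character vector of physical units (default uV for
#'   EEG/EOG, mV for ECG).
#' @return an object of class `signal_recording`.
#' @export
signal_recording <- function(signals, rates, roles, units = NULL) {
  stopifnot(is.list(signals), length(signals) > 0,
            !is.null(names(signals)))
  ch <- names(signals)
  rates <- rates[ch]; roles <- roles[ch]
  if (anyNA(rates) || anyNA(roles))
    stop("every channel needs a rate and a role")
  if (!all(roles %in% c("EEG", "EOG", "ECG")))
    stop("roles must be EEG, EOG or ECG")
  if (is.null(units))
    units <- stats::setNames(ifelse(roles == "ECG", "mV", "uV"), ch)
  dur <- vapply(ch, function(nm) length(signals[[nm]]) / rates[[nm]],
                numeric(1))
  if (diff(range(dur)) > 1 / min(rates) + 1e-9)
    stop("channel durations disagree")
  structure(list(signals = signals, rates = rates, roles = roles,
                 units = units[ch], duration = max(dur)),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %d channels, %.1f s\n",
              length(x$signals), x$duration))
  for (nm in names(x$signals))
    cat(sprintf("  %-8s %-4s %g Hz, %d samples\n", nm, x$roles[[nm]],
                x$rates[[nm]], length(x$signals[[nm]])))
  invisible(x)
}

#' Channels of a recording having a given role
#'
#' @param rec a `signal_recording`.
#' @param role one of "EEG", "EOG", "ECG".
#' @return character vector of channel names (possibly empty).
#' @export
channels_by_role <- function(rec, role) {
  names(rec$roles)[rec$roles == role]
}

#' Construct a hypnogram
#'
#' @param stages character vector of stage labels over the fixed vocabulary
#'   WAKE, N1, N2, N3, REM; one entry per 20 s epoch.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) == 0) stop("empty hypnogram")
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad))
    stop("unknown sleep stages: ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_sec = EPOCH_SEC,
                 duration = length(stages) * EPOCH_SEC),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat(sprintf("<hypnogram> %d epochs (%.2f h): %s\n", length(x$stages),
              x$duration / 3600,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Stage label at given times
#'
#' @param hyp a `hypnogram`.
#' @param t numeric vector of times in seconds.
#' @return character vector of stages (half-open epoch convention).
#' @export
stage_at <- function(hyp, t) {
  idx <- pmin(floor(t / hyp$epoch_sec) + 1, length(hyp$stages))
  hyp$stages[pmax(idx, 1)]
}

#' Per-sample stage vector for a channel sampled at `rate`
#' @keywords internal
stage_samples <- function(hyp, rate) {
  rep(hyp$stages, each = hyp$epoch_sec * rate)
}
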