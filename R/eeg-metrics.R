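# EEG analysis chain: Welch spectra and SHAM-referenced percentage change,
# Hilbert slow-wave dynamics, 5 s sub-window SWA, spindle detection and
# 2 s-bin spindle probability, baseline-SWA pairing, early/late night split.

#' Standard analysis frequency bands
#'
#' @return named list of band edges (Hz): low SWA 0.5-2, high SWA 2.25-4.5,
#'   low alpha 8-10, slow spindles 10-12, fast spindles 13-16, spindle
#'   detection 10-16.
#' @export
band_set <- function() {
  list(low_swa = c(0.5, 2), high_swa = c(2.25, 4.5), low_alpha = c(8, 10),
       slow_spindle = c(10, 12), fast_spindle = c(13, 16),
       spindle_detect = c(10, 16))
}

#' Welch power spectral density
#'
#' Hann windows of `window_sec` seconds (default 4, giving 0.25 Hz
#' resolution) with 50% overlap; one-sided density scaled so that
#' `sum(power) * df` equals the signal's mean square (Parseval).
#'
#' @param x numeric segment, at least `window_sec` long.
#' @param rate sampling rate (Hz).
#' @param window_sec Hann window length (s).
#' @param overlap fractional overlap (default 0.5).
#' @param normalize "none" or "cumulative_to_30Hz" (each spectrum divided by
#'   the sum of its bins at or below 30 Hz).
#' @return data.frame with `freq` (Hz) and `power`; attributes `rate`,
#'   `normalization`, `n_segments`.
#' @export
welch_psd <- function(x, rate, window_sec = 4, overlap = 0.5,
                      normalize = c("none", "cumulative_to_30Hz")) {
  normalize <- match.arg(normalize)
  nw <- round(window_sec * rate)
  if (length(x) < nw)
    stop("segment shorter than the Welch window (", window_sec, " s)")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / nw)   # periodic Hann
  scale <- rate * sum(w^2)
  nf <- floor(nw / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / scale
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nw)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nw %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  freq <- seq(0, nf - 1) * rate / nw
  if (normalize == "cumulative_to_30Hz") {
    tot <- sum(p[freq <= 30])
    if (tot > 0) p <- p / tot
  }
  out <- data.frame(freq = freq, power = p)
  attr(out, "rate") <- rate
  attr(out, "normalization") <- normalize
  attr(out, "n_segments") <- length(starts)
  out
}

#' Band power from a Welch spectrum
#'
#' @param psd data.frame from [welch_psd()].
#' @param band length-2 Hz range (half-open `[lo, hi)` on bin centres;
#'   inclusive of the lower edge).
#' @return sum of `power * df` over the band.
#' @export
psd_band_power <- function(psd, band) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9
  sum(psd$power[sel]) * df
}

#' Per-bin percentage PSD change of a condition versus SHAM
#'
#' `100 * (cond - sham) / sham` per frequency bin; bins where the SHAM
#' power is zero are returned as NA (flagged, excluded downstream).
#'
#' @param cond,sham data.frames from [welch_psd()] on identical frequency
#'   grids.
#' @return data.frame with `freq`, `pct_change`.
#' @export
psd_percent_change <- function(cond, sham) {
  if (nrow(cond) != nrow(sham) ||
      max(abs(cond$freq - sham$freq)) > 1e-9)
    stop("frequency grids do not match")
  pct <- ifelse(sham$power == 0, NA_real_,
                100 * (cond$power - sham$power) / sham$power)
  data.frame(freq = cond$freq, pct_change = pct)
}

# Zero-phase FIR band-pass: Hamming-windowed sinc, order from the
# transition-width rule (transition = max(band[1]/2, 0.25) Hz), applied via
# FFT convolution with group-delay compensation.
fir_bandpass <- function(x, rate, band, order = NULL) {
  if (is.null(order)) {
    trans <- max(band[1] / 2, 0.25)
    order <- ceiling(3.3 * rate / trans / 2) * 2     # even order
  }
  b <- signal::fir1(order, band / (rate / 2), type = "pass")
  half <- order / 2
  xp <- c(mirror_pad(x, half), numeric(half))
  y <- as.numeric(signal::fftfilt(b, c(xp, numeric(order))))
  y[(half + order / 2 + 1):(half + order / 2 + length(x))]
}

# Per-sample indices of a window-relative time grid.
window_grid <- function(window, rate) {
  n <- round((window$on_dur + window$off_dur) * rate)
  i0 <- round(window$on_start * rate) + 1
  seq(i0, i0 + n - 1)
}

#' Hilbert slow-wave dynamics of stimulation windows
#'
#' Band-passes the channel with a zero-phase FIR filter, extracts the
#' analytic (Hilbert) amplitude, averages it per time point across each
#' condition's valid windows, and expresses each condition as the
#' percentage change against the SHAM per-timepoint mean.
#'
#' @param x numeric EEG channel.
#' @param rate sampling rate (Hz).
#' @param windows a `stim_windows` table (invalid windows are skipped).
#' @param band Hz, default low SWA 0.5-2.
#' @param grid_rate output grid rate (Hz, default 50; amplitude is smooth).
#' @return data.frame with `time` (s from ON onset), `condition`,
#'   `mean_amp`, `pct_change` (vs SHAM; NA for the SHAM rows themselves),
#'   `sem_pct`, `n` (windows used).
#' @export
hilbert_dynamics <- function(x, rate, windows, band = c(0.5, 2),
                             grid_rate = 50) {
  use <- windows[windows$valid, , drop = FALSE]
  conds <- unique(use$condition)
  dec <- max(1L, round(rate / grid_rate))
  env <- Mod(analytic_signal(fir_bandpass(x, rate, band)))
  per_cond <- list()
  for (cond in conds) {
    w <- use[use$condition == cond, , drop = FALSE]
    mats <- lapply(seq_len(nrow(w)), function(i) {
      idx <- window_grid(w[i, ], rate)
      idx <- idx[idx >= 1 & idx <= length(env)]
      env[idx][seq(1, length(idx), by = dec)]
    })
    len <- min(lengths(mats))
    M <- do.call(rbind, lapply(mats, function(v) v[seq_len(len)]))
    per_cond[[cond]] <- M
  }
  if (!"SHAM" %in% names(per_cond) || is.null(per_cond$SHAM))
    stop("no valid SHAM windows: cannot reference the dynamics")
  sham_mean <- colMeans(per_cond$SHAM)
  out <- list()
  for (cond in names(per_cond)) {
    M <- per_cond[[cond]]
    len <- min(ncol(M), length(sham_mean))
    mu <- colMeans(M[, seq_len(len), drop = FALSE])
    ref <- sham_mean[seq_len(len)]
    pct <- 100 * (mu - ref) / ref
    sem_amp <- apply(M[, seq_len(len), drop = FALSE], 2, stats::sd) /
      sqrt(nrow(M))
    out[[cond]] <- data.frame(
      time = (seq_len(len) - 1) * dec / rate,
      condition = cond, mean_amp = mu,
      pct_change = if (cond == "SHAM") NA_real_ else pct,
      sem_pct = 100 * sem_amp / ref, n = nrow(M))
  }
  do.call(rbind, out)
}

#' SWA of the four 5 s sub-windows of each stimulation window
#'
#' The 20 s stimulation window is split into ON[0,5), ON[5,10), OFF[0,5),
#' OFF[5,10); each 5 s segment's band power comes from a Welch estimate
#' with 2 s Hann sub-segments (a 4 s window cannot tile 5 s).
#'
#' @param x numeric EEG channel.
#' @param rate sampling rate (Hz).
#' @param windows a `stim_windows` table.
#' @param band Hz, default low SWA.
#' @return data.frame: `window_id`, `condition`, `sub` (ON1/ON2/OFF1/OFF2),
#'   `swa`.
#' @export
swa_subwindows <- function(x, rate, windows, band = c(0.5, 2)) {
  subs <- c(ON1 = 0, ON2 = 5, OFF1 = 10, OFF2 = 15)
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    for (s in names(subs)) {
      i0 <- round((w$on_start + subs[[s]]) * rate) + 1
      i1 <- min(i0 + round(5 * rate) - 1, length(x))
      psd <- welch_psd(x[i0:i1], rate, window_sec = 2)
      rows[[length(rows) + 1]] <-
        data.frame(window_id = w$window_id, condition = w$condition,
                   sub = s, swa = psd_band_power(psd, band))
    }
  }
  do.call(rbind, rows)
}

#' Detect sleep spindles
#'
#' Forward-backward Chebyshev type-I band-pass 10-16 Hz, analytic-amplitude
#' envelope (lightly smoothed), candidate events where the envelope exceeds
#' twice its recording mean; events whose envelope exceeds five times the
#' mean are rejected as artifacts.  Events closer than `merge_gap` are
#' merged and events shorter than `min_dur` discarded.  The event start and
#' peak frequency (mean instantaneous frequency over the event) are
#' returned.
#'
#' @param x numeric EEG channel (several minutes at least, so the mean
#'   envelope is estimable).
#' @param rate sampling rate (Hz).
#' @param band detection band (default 10-16 Hz).
#' @param lower,upper envelope thresholds in multiples of the mean envelope
#'   (default 2 and 5).
#' @param extent events detected at `lower` are grown outward to where the
#'   envelope falls below this multiple of the mean (event boundaries).
#' @param min_core minimum sustained time above `lower` (s); rejects brief
#'   noise excursions.
#' @param min_dur minimum event duration after extent growth (s).
#' @param merge_gap merge events separated by less than this (s).
#' @param smooth_sec envelope smoothing (s).
#' @return data.frame with `start`, `duration`, `freq`, `peak_env` (possibly
#'   zero rows).
#' @export
detect_spindles <- function(x, rate, band = c(10, 16), lower = 2, upper = 5,
                            extent = 1.25, min_core = 0.25, min_dur = 0.3,
                            merge_gap = 0.25, smooth_sec = 0.2) {
  empty <- data.frame(start = numeric(0), duration = numeric(0),
                      freq = numeric(0), peak_env = numeric(0))
  if (all(x == 0)) return(empty)
  cf <- signal::cheby1(4, 0.5, band / (rate / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(cf, x))
  z <- analytic_signal(y)
  env <- Mod(z)
  k <- max(1L, round(smooth_sec * rate))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  me <- mean(env)
  if (me == 0) return(empty)
  core <- env > lower * me
  if (!any(core)) return(empty)
  ext <- env > extent * me
  # grow each core run outward to the extent-threshold boundaries
  r <- rle(ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  core_run <- function(j) {
    cr <- rle(core[runs$i0[j]:runs$i1[j]])
    any(cr$values & cr$lengths >= min_core * rate)
  }
  has_core <- vapply(seq_len(nrow(runs)), core_run, logical(1))
  ev <- runs[has_core, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  if (nrow(ev) > 1) {
    keep <- list(ev[1, ])
    for (j in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if ((ev$i0[j] - last$i1) / rate < merge_gap)
        keep[[length(keep)]]$i1 <- ev$i1[j]
      else keep[[length(keep) + 1]] <- ev[j, ]
    }
    ev <- do.call(rbind, keep)
  }
  dur <- (ev$i1 - ev$i0 + 1) / rate
  ev <- ev[dur >= min_dur, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  phase <- Arg(z)
  res <- lapply(seq_len(nrow(ev)), function(j) {
    idx <- ev$i0[j]:ev$i1[j]
    pk <- max(env[idx])
    if (pk > upper * me) return(NULL)            # artifact rejection
    dph <- diff(unwrap_phase(phase[idx]))
    data.frame(start = (ev$i0[j] - 1) / rate,
               duration = (ev$i1[j] - ev$i0[j] + 1) / rate,
               freq = stats::median(dph) * rate / (2 * pi),
               peak_env = pk)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

#' Mean spindle-band envelope of a recording
#'
#' The smoothed analytic-amplitude mean that [detect_spindles()] thresholds
#' against; exposed so that simulation studies can calibrate injected
#' spindle amplitudes in the detector's own units.
#'
#' @inheritParams detect_spindles
#' @return scalar mean envelope.
#' @export
spindle_background <- function(x, rate, band = c(10, 16),
                               smooth_sec = 0.2) {
  cf <- signal::cheby1(4, 0.5, band / (rate / 2), type = "pass")
  env <- Mod(analytic_signal(as.numeric(signal::filtfilt(cf, x))))
  k <- max(1L, round(smooth_sec * rate))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  mean(env, na.rm = TRUE)
}

#' Spindle probability per 2 s bin of the stimulation window
#'
#' For every valid 20 s stimulation window, each of the ten 2 s bins scores
#' 1 if at least one detected spindle starts inside it (multiple starts
#' still count 1); the probability is the per-bin sum divided by the number
#' of valid windows.
#'
#' @param events spindle table from [detect_spindles()].
#' @param windows a `stim_windows` table with at least one valid window.
#' @param bin_sec bin width (s, default 2).
#' @return data.frame with `bin_start` (s from ON onset), `probability`.
#' @export
spindle_probability <- function(events, windows, bin_sec = 2) {
  use <- windows[windows$valid, , drop = FALSE]
  if (!nrow(use)) stop("no valid stimulation windows")
  total <- use$on_dur[1] + use$off_dur[1]
  nbins <- floor(total / bin_sec)
  counts <- numeric(nbins)
  for (i in seq_len(nrow(use))) {
    rel <- events$start - use$on_start[i]
    rel <- rel[rel >= 0 & rel < total]
    bins <- unique(floor(rel / bin_sec) + 1)
    counts[bins] <- counts[bins] + 1
  }
  data.frame(bin_start = (seq_len(nbins) - 1) * bin_sec,
             probability = counts / nrow(use))
}

#' Baseline SWA versus first-5 s SWA enhancement pairs
#'
#' For every valid ISI1 window with a valid SHAM window within `radius`
#' (default 5 min), returns the low-SWA of the 5 s pre-ON baseline and the
#' percentage change of the first-5 s ON SWA against the paired SHAM
#' window's first-5 s ON SWA.  Windows without a qualifying SHAM are
#' dropped; ties go to the earlier SHAM window.
#'
#' @param x numeric EEG channel.
#' @param rate sampling rate (Hz).
#' @param windows a `stim_windows` table.
#' @param isi1_conditions condition labels treated as ISI1 (default the
#'   three ISI1 variants).
#' @param band Hz, default low SWA.
#' @param radius pairing radius (s, default 300).
#' @return data.frame: `window_id`, `condition`, `baseline_swa`,
#'   `pct_change`, `sham_id`.
#' @export
baseline_swa_pairs <- function(x, rate, windows,
                               isi1_conditions = c("ISI1_High", "ISI1_Low",
                                                   "ISI1_Mod"),
                               band = c(0.5, 2), radius = 300) {
  use <- windows[windows$valid, , drop = FALSE]
  isi <- use[use$condition %in% isi1_conditions, , drop = FALSE]
  sham <- use[use$condition == "SHAM", , drop = FALSE]
  swa5 <- function(t0) {
    i0 <- round(t0 * rate) + 1
    i1 <- min(i0 + round(5 * rate) - 1, length(x))
    if (i0 < 1 || i1 - i0 + 1 < 2 * rate) return(NA_real_)
    psd_band_power(welch_psd(x[i0:i1], rate, window_sec = 2), band)
  }
  rows <- list()
  for (i in seq_len(nrow(isi))) {
    w <- isi[i, ]
    if (!nrow(sham)) next
    d <- abs(sham$on_start - w$on_start)
    ok <- which(d <= radius)
    if (!length(ok)) next
    j <- ok[order(d[ok], sham$on_start[ok])][1]
    base <- swa5(w$on_start - 5)
    a <- swa5(w$on_start)
    b <- swa5(sham$on_start[j])
    if (anyNA(c(base, a, b)) || b == 0) next
    rows[[length(rows) + 1]] <-
      data.frame(window_id = w$window_id, condition = w$condition,
                 baseline_swa = base, pct_change = 100 * (a - b) / b,
                 sham_id = sham$window_id[j])
  }
  if (!length(rows))
    return(data.frame(window_id = integer(0), condition = character(0),
                      baseline_swa = numeric(0), pct_change = numeric(0),
                      sham_id = integer(0)))
  do.call(rbind, rows)
}

#' Split stimulation windows into early and late night
#'
#' Early = windows starting within the first 4 h counted from the first ON
#' window; late = the rest.  Half-open convention: a window exactly at
#' +4 h is late.
#'
#' @param windows a `stim_windows` table with at least one row.
#' @param first_on reference time (s); default the earliest ON onset.
#' @param hours split point (default 4).
#' @return list with `early` and `late` window tables.
#' @export
split_early_late <- function(windows, first_on = NULL, hours = 4) {
  if (!nrow(windows)) stop("no stimulation windows")
  if (is.null(first_on)) first_on <- min(windows$on_start)
  cut <- first_on + hours * 3600
  list(early = windows[windows$on_start < cut, , drop = FALSE],
       late = windows[windows$on_start >= cut, , drop = FALSE])
}

#' Mark windows valid if they lie in artifact-free N2/N3
#'
#' A window is valid when every epoch it overlaps is N2 or N3 and no
#' movement artifact (ground truth or detected) intersects it.
#'
#' @param windows a `stim_windows` table.
#' @param hyp a `hypnogram`.
#' @param movements optional data.frame with `start`, `duration`.
#' @return the window table with the `valid` flag updated.
#' @export
mark_valid_windows <- function(windows, hyp, movements = NULL) {
  for (i in seq_len(nrow(windows))) {
    t0 <- windows$on_start[i]
    t1 <- t0 + windows$on_dur[i] + windows$off_dur[i]
    ep <- unique(stage_at(hyp, seq(t0, t1 - 1e-6, by = hyp$epoch_sec / 2)))
    ok <- all(ep %in% c("N2", "N3"))
    if (ok && !is.null(movements) && nrow(movements))
      ok <- !any(movements$start < t1 &
                   movements$start + movements$duration > t0)
    windows$valid[i] <- ok
  }
  windows
}
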