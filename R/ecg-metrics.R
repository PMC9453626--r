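# Cardiovascular chain: R-peak detection, per-window RR extraction, HRV
# features (RMSSD, SDNN, extrema), continuous instantaneous heart rate and
# SHAM-referenced percentage IHR change.

#' Construct an RR-interval series
#'
#' @param r_times strictly increasing R-peak times (s).
#' @param quality optional logical per interval (default all good);
#'   excluded segments are marked, not deleted.
#' @return an `rr_series` with `r_times` (s), `rr` (ms) and `quality`.
#' @export
rr_series <- function(r_times, quality = NULL) {
  r_times <- as.numeric(r_times)
  if (is.unsorted(r_times, strictly = TRUE))
    stop("R-peak times must be strictly increasing")
  rr <- diff(r_times) * 1000
  if (any(rr <= 0)) stop("non-positive RR interval")
  if (is.null(quality)) quality <- rep(TRUE, length(rr))
  stopifnot(length(quality) == length(rr))
  structure(list(r_times = r_times, rr = rr, quality = quality),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, mean RR %.1f ms (%.1f bpm)\n",
              length(x$r_times), mean(x$rr), 60000 / mean(x$rr)))
  invisible(x)
}

#' Detect R peaks in an ECG trace
#'
#' Band-pass 5-25 Hz (QRS energy), absolute value (polarity-robust), 30 ms
#' smoothing, then peak picking above an adaptive threshold with a 250 ms
#' refractory period.
#'
#' @param x numeric ECG vector.
#' @param rate sampling rate (Hz), at least 250.
#' @param threshold_frac detection threshold as a fraction of the 98th
#'   percentile of the smoothed detection function (default 0.4).
#' @return an `rr_series` (empty `r_times` if the trace is flat).
#' @export
detect_r_peaks <- function(x, rate, threshold_frac = 0.4) {
  stopifnot(rate >= 250)
  if (stats::sd(x) == 0)
    return(structure(list(r_times = numeric(0), rr = numeric(0),
                          quality = logical(0), flat = TRUE),
                     class = "rr_series"))
  y <- abs(bandpass(x, rate, c(5, 25), order = 2))
  k <- max(1L, round(0.03 * rate))
  y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  y[is.na(y)] <- 0
  thr <- threshold_frac * stats::quantile(y, 0.98, names = FALSE)
  refr <- round(0.25 * rate)
  above <- which(y > thr)
  if (!length(above)) return(rr_series(numeric(0)))
  peaks <- integer(0)
  i <- 1
  while (i <= length(above)) {
    j <- i
    while (j < length(above) && above[j + 1] - above[j] <= refr / 4)
      j <- j + 1
    seg <- above[i]:above[j]
    pk <- seg[which.max(y[seg])]
    if (!length(peaks) || pk - peaks[length(peaks)] > refr)
      peaks <- c(peaks, pk)
    i <- j + 1
  }
  rr_series((peaks - 1) / rate)
}

#' RR intervals fully inside a stimulation window
#'
#' Keeps only intervals whose both bounding R peaks lie inside
#' `[on_start, on_start + on_dur + off_dur)`.
#'
#' @param rr an `rr_series`.
#' @param window one row of a `stim_windows` table.
#' @return an `rr_series` subset (possibly empty); attribute `hrv_valid`
#'   FALSE when fewer than 2 peaks fall in the window.
#' @export
window_rr <- function(rr, window) {
  t0 <- window$on_start
  t1 <- t0 + window$on_dur + window$off_dur
  inside <- rr$r_times >= t0 & rr$r_times < t1
  idx <- which(inside)
  if (length(idx) < 2) {
    out <- structure(list(r_times = rr$r_times[idx], rr = numeric(0),
                          quality = logical(0)), class = "rr_series")
    attr(out, "hrv_valid") <- FALSE
    return(out)
  }
  keep <- idx[-length(idx)]            # intervals bounded inside
  out <- structure(list(r_times = rr$r_times[idx],
                        rr = rr$rr[keep], quality = rr$quality[keep]),
                   class = "rr_series")
  attr(out, "hrv_valid") <- TRUE
  out
}

#' Per-window HRV features
#'
#' RMSSD = sqrt(mean of squared successive RR differences); SDNN = sample
#' (n-1) standard deviation of the RR intervals; plus the mean, longest and
#' shortest interval and their difference.  Only intervals whose quality
#' flag is TRUE enter.
#'
#' @param rr an `rr_series` (typically from [window_rr()]).
#' @return one-row data.frame: `mean_rr`, `longest_rr`, `shortest_rr`,
#'   `rr_diff`, `rmssd`, `sdnn`, `n_intervals` (NA features when fewer than
#'   2 usable intervals).
#' @export
hrv_features <- function(rr) {
  v <- rr$rr[rr$quality]
  n <- length(v)
  if (n < 2)
    return(data.frame(mean_rr = if (n) mean(v) else NA_real_,
                      longest_rr = NA_real_, shortest_rr = NA_real_,
                      rr_diff = NA_real_, rmssd = NA_real_, sdnn = NA_real_,
                      n_intervals = n))
  data.frame(mean_rr = mean(v), longest_rr = max(v), shortest_rr = min(v),
             rr_diff = max(v) - min(v),
             rmssd = sqrt(mean(diff(v)^2)),
             sdnn = stats::sd(v), n_intervals = n)
}

#' Continuous instantaneous heart rate over a stimulation window
#'
#' IHR samples `60 / RR(s)` are anchored at the closing R peak of each
#' interval and resampled to a uniform grid with a shape-preserving
#' monotone cubic interpolant (no overshoot beyond neighbouring samples).
#' The last 2 s of the 20 s window are dropped, so the trace covers the ON
#' window plus the first 8 s of OFF.
#'
#' @param rr an `rr_series` restricted to the window (see [window_rr()]).
#' @param window one row of a `stim_windows` table.
#' @param grid_rate output rate (Hz, default 4).
#' @param max_gap flag the trace invalid when consecutive usable IHR
#'   samples are more than this many seconds apart (default 3).
#' @param anchor "close" (closing R peak, default) or "mid" (interval
#'   midpoint).
#' @return data.frame with `time` (s, absolute), `ihr` (bpm); attribute
#'   `ihr_valid`.
#' @export
ihr_continuous <- function(rr, window, grid_rate = 4, max_gap = 3,
                           anchor = c("close", "mid")) {
  anchor <- match.arg(anchor)
  use <- which(rr$quality)
  if (length(use) < 3) {
    out <- data.frame(time = numeric(0), ihr = numeric(0))
    attr(out, "ihr_valid") <- FALSE
    return(out)
  }
  t_anchor <- if (anchor == "close") rr$r_times[use + 1] else
    (rr$r_times[use] + rr$r_times[use + 1]) / 2
  ihr <- 60 / (rr$rr[use] / 1000)
  t_end <- window$on_start + window$on_dur + window$off_dur - 2
  grid <- seq(window$on_start, t_end, by = 1 / grid_rate)
  f <- stats::splinefun(t_anchor, ihr, method = "monoH.FC")
  vals <- f(pmin(pmax(grid, t_anchor[1]), t_anchor[length(t_anchor)]))
  out <- data.frame(time = grid, ihr = vals)
  attr(out, "ihr_valid") <- max(diff(t_anchor)) <= max_gap
  out
}

#' SHAM-referenced percentage IHR change
#'
#' For every non-SHAM window with a SHAM window within `radius` (default
#' 5 min, inclusive; ties go to the earlier SHAM), the reference is the
#' mean heart rate of that SHAM window and the trace is
#' `100 * (IHR - ref) / ref` per time point.  Windows without a qualifying
#' SHAM are dropped.
#'
#' @param rr an `rr_series` for the whole recording.
#' @param windows a `stim_windows` table.
#' @param grid_rate output rate (Hz).
#' @return data.frame: `window_id`, `condition`, `rel_time` (s from ON
#'   onset), `pct_change`, `sham_id`; zero rows (with a warning) when no
#'   SHAM exists.
#' @export
relative_ihr <- function(rr, windows, grid_rate = 4, radius = 300) {
  use <- windows[windows$valid, , drop = FALSE]
  sham <- use[use$condition == "SHAM", , drop = FALSE]
  cond <- use[use$condition != "SHAM", , drop = FALSE]
  empty <- data.frame(window_id = integer(0), condition = character(0),
                      rel_time = numeric(0), pct_change = numeric(0),
                      sham_id = integer(0))
  if (!nrow(sham)) {
    warning("no SHAM window in the night: all windows dropped")
    return(empty)
  }
  sham_mean_hr <- vapply(seq_len(nrow(sham)), function(j) {
    sub <- window_rr(rr, sham[j, ])
    if (!isTRUE(attr(sub, "hrv_valid"))) return(NA_real_)
    mean(60 / (sub$rr[sub$quality] / 1000))
  }, numeric(1))
  rows <- list()
  for (i in seq_len(nrow(cond))) {
    w <- cond[i, ]
    d <- abs(sham$on_start - w$on_start)
    ok <- which(d <= radius & !is.na(sham_mean_hr))
    if (!length(ok)) next
    j <- ok[order(d[ok], sham$on_start[ok])][1]
    sub <- window_rr(rr, w)
    if (!isTRUE(attr(sub, "hrv_valid"))) next
    tr <- ihr_continuous(sub, w, grid_rate = grid_rate)
    if (!nrow(tr)) next
    ref <- sham_mean_hr[j]
    rows[[length(rows) + 1]] <-
      data.frame(window_id = w$window_id, condition = w$condition,
                 rel_time = tr$time - w$on_start,
                 pct_change = 100 * (tr$ihr - ref) / ref,
                 sham_id = sham$window_id[j])
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' HRV features for every stimulation window
#'
#' @param rr an `rr_series` for the whole recording.
#' @param windows a `stim_windows` table.
#' @return data.frame of [hrv_features()] rows with `window_id` and
#'   `condition` prepended.
#' @export
window_hrv <- function(rr, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    f <- hrv_features(window_rr(rr, windows[i, ]))
    cbind(data.frame(window_id = windows$window_id[i],
                     condition = windows$condition[i]), f)
  })
  do.call(rbind, rows)
}
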