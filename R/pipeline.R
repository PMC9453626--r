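# End-to-end pipeline driver: synthetic night -> closed-loop engine ->
# EEG + ECG metrics -> statistics, with tidy CSV outputs and a JSON run
# manifest.  All event times are seconds from recording start, intervals
# half-open [start, end).

#' Pipeline run configuration
#'
#' @param input "synthetic" (default) or the path of an EDF recording.
#' @param duration_h synthetic night length in hours.
#' @param synth a `synth_params` (default [synth_params()] with `seed`).
#' @param detector a `detector_config`.
#' @param conditions condition names for the roster (see
#'   [default_conditions()]).
#' @param pairing_radius SHAM-pairing radius in seconds (default 300).
#' @param seed master seed; drives generator and sequencer.
#' @param out_dir output directory (NULL = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(input = "synthetic", duration_h = 0.5,
                       synth = NULL, detector = NULL,
                       conditions = c("UP", "DOWN", "ISI1_High", "ENVELOPE",
                                      "BINAURAL_BEATS", "SHAM"),
                       pairing_radius = 300, seed = 1L, out_dir = NULL) {
  if (is.null(synth)) synth <- synth_params(seed = seed)
  if (is.null(detector)) detector <- detector_config()
  structure(list(input = input, duration_h = duration_h, synth = synth,
                 detector = detector, conditions = conditions,
                 pairing_radius = pairing_radius, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' `load_config(save_config(cfg, path))` reproduces the configuration.
#'
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @return `path` (save) or a `run_config` (load).
#' @export
save_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$synth <- unclass(plain$synth)
  plain$detector <- unclass(plain$detector)
  # jsonlite drops the names of named atomic vectors; stage maps must
  # survive the round trip as objects
  for (f in c("so_amp_by_stage", "delta_amp_by_stage",
              "beta_amp_by_stage"))
    plain$synth[[f]] <- as.list(plain$synth[[f]])
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- plain$synth
  synth <- synth_params(
    sampling_rate = sp$sampling_rate, so_freq = sp$so_freq,
    so_band = sp$so_band, so_amp_by_stage = unlist(sp$so_amp_by_stage),
    delta_amp_by_stage = unlist(sp$delta_amp_by_stage),
    beta_amp_by_stage = unlist(sp$beta_amp_by_stage),
    spindle_rate = sp$spindle_rate,
    spindle_freq_range = sp$spindle_freq_range,
    spindle_dur_range = sp$spindle_dur_range,
    spindle_amp = sp$spindle_amp,
    spindle_amp_jitter = sp$spindle_amp_jitter,
    noise_exponent = sp$noise_exponent,
    noise_amp = sp$noise_amp, eog_defl_rate = sp$eog_defl_rate,
    movement_rate = sp$movement_rate, movement_amp = sp$movement_amp,
    stim_response = sp$stim_response, cardiac = sp$cardiac,
    so_preset = sp$so_preset, seed = sp$seed)
  dc <- plain$detector
  detector <- detector_config(
    bands = dc$bands, first_stable_nrem = dc$first_stable_nrem,
    later_stable_nrem = dc$later_stable_nrem,
    movement_holdoff = dc$movement_holdoff,
    power_window = dc$power_window, update_step = dc$update_step,
    beta_k = dc$beta_k, eog_anticorr_cut = dc$eog_anticorr_cut,
    eog_window = dc$eog_window, movement_amp_cut = dc$movement_amp_cut,
    delta_gate_quantile = dc$delta_gate_quantile,
    nrem_ratio_cut = dc$nrem_ratio_cut, so_band = dc$so_band,
    pll_rate = dc$pll_rate, pll = dc$pll,
    stim_channel = dc$stim_channel)
  run_config(input = plain$input, duration_h = plain$duration_h,
             synth = synth, detector = detector,
             conditions = plain$conditions,
             pairing_radius = plain$pairing_radius, seed = plain$seed,
             out_dir = plain$out_dir)
}

#' Run the full pipeline
#'
#' Synthetic generation (if requested), the closed-loop engine, window
#' validation against the hypnogram, stimulus-response injection, the RR
#' series, the EEG and ECG metric chains and summary statistics.  With an
#' output directory the tidy CSVs and a JSON manifest (seed, config hash,
#' per-stage window counters, failure point if any) are written; runs are
#' idempotent given the seed.
#'
#' @param config a `run_config`.
#' @return (invisibly) a result bundle: `hypnogram`, `recording`, `truth`,
#'   `windows`, `tones`, `rr`, `dynamics`, `swa`, `spindles`,
#'   `spindle_prob`, `baseline_pairs`, `hrv`, `ihr_change`, `stats`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- list(manifest = list(seed = config$seed,
                              conditions = config$conditions,
                              failed_at = NULL, counters = list()))
  stage <- function(name, expr) {
    if (!is.null(out$manifest$failed_at)) return(NULL)
    tryCatch(expr, error = function(e) {
      out$manifest$failed_at <<- paste0(name, ": ", conditionMessage(e))
      NULL
    })
  }

  if (identical(config$input, "synthetic")) {
    out$hypnogram <- stage("hypnogram",
      generate_hypnogram(config$duration_h, seed = config$seed))
    gen <- stage("eeg", generate_eeg(out$hypnogram, config$synth))
    rec <- gen$recording; truth <- gen$truth
  } else {
    rec <- stage("read", read_recording(config$input))
    truth <- NULL
    out$hypnogram <- NULL
  }

  conds <- default_conditions(config$conditions)
  eng <- stage("engine", run_stim_engine(rec, config$detector, conds,
                                         seed = config$seed))
  windows <- eng$windows
  if (!is.null(out$hypnogram) && !is.null(windows))
    windows <- mark_valid_windows(windows, out$hypnogram,
                                  truth$movements)
  out$windows <- windows
  out$tones <- eng$tones
  out$manifest$counters$scheduled <- if (is.null(windows)) 0 else
    nrow(windows)
  out$manifest$counters$valid <- if (is.null(windows)) 0 else
    sum(windows$valid)

  if (!is.null(truth)) {
    inj <- stage("inject",
      inject_stim_response(rec, windows, config$synth, truth))
    rec <- inj$recording; truth <- inj$truth
    rrg <- stage("rr", generate_rr(rec$duration, windows, config$synth))
    out$rr_truth <- rrg$truth
    ecg_rec <- rrg$ecg
  } else {
    ecg_rec <- rec
  }
  out$recording <- rec
  out$truth <- truth

  ch <- channels_by_role(rec, "EEG")[1]
  x <- rec$signals[[ch]]; fs <- rec$rates[[ch]]

  out$dynamics <- stage("dynamics", hilbert_dynamics(x, fs, windows))
  vw <- windows[windows$valid, , drop = FALSE]
  out$swa <- stage("swa", if (nrow(vw)) swa_subwindows(x, fs, vw))
  out$spindles <- stage("spindles", detect_spindles(x, fs))
  out$spindle_prob <- stage("spindle_prob",
    if (nrow(vw)) spindle_probability(out$spindles, vw))
  out$baseline_pairs <- stage("baseline_pairs",
    baseline_swa_pairs(x, fs, windows, radius = config$pairing_radius))

  ecg_ch <- channels_by_role(ecg_rec, "ECG")[1]
  rr <- stage("rpeaks", detect_r_peaks(ecg_rec$signals[[ecg_ch]],
                                       ecg_rec$rates[[ecg_ch]]))
  out$rr <- rr
  out$hrv <- stage("hrv", if (!is.null(rr) && nrow(windows))
    window_hrv(rr, windows))
  out$ihr_change <- stage("ihr",
    relative_ihr(rr, windows, radius = config$pairing_radius))
  out$manifest$counters$paired <- if (is.null(out$ihr_change)) 0 else
    length(unique(out$ihr_change$window_id))

  out$stats <- stage("stats", pipeline_stats(out))
  out$manifest$config_hash <- config_hash(config)

  if (!is.null(config$out_dir)) write_bundle(out, config)
  invisible(out)
}

# Paired contrasts of per-window HRV features against each window's paired
# SHAM (nearest valid SHAM within the pairing radius), Hochberg-adjusted.
pipeline_stats <- function(out) {
  hrv <- out$hrv; w <- out$windows
  if (is.null(hrv) || is.null(w)) return(NULL)
  vw <- w[w$valid, , drop = FALSE]
  sham <- vw[vw$condition == "SHAM", , drop = FALSE]
  if (!nrow(sham)) return(NULL)
  rows <- list()
  feats <- c("mean_rr", "longest_rr", "rmssd", "sdnn")
  for (cond in setdiff(unique(vw$condition), "SHAM")) {
    cw <- vw[vw$condition == cond, , drop = FALSE]
    pair <- vapply(cw$on_start, function(t0) {
      d <- abs(sham$on_start - t0)
      if (min(d) > 300) NA_integer_ else
        sham$window_id[order(d, sham$on_start)][1]
    }, integer(1))
    keep <- !is.na(pair)
    if (sum(keep) < 2) next
    a <- hrv[match(cw$window_id[keep], hrv$window_id), ]
    b <- hrv[match(pair[keep], hrv$window_id), ]
    for (f in feats) {
      ok <- stats::complete.cases(a[[f]], b[[f]])
      if (sum(ok) < 2) next
      ct <- paired_contrast(a[[f]][ok], b[[f]][ok])
      rows[[length(rows) + 1]] <-
        data.frame(term = paste0(cond, " vs SHAM"), feature = f,
                   estimate = ct$mean_diff, statistic = ct$t, df = ct$df,
                   p = ct$p, n = sum(ok))
    }
  }
  if (!length(rows)) return(NULL)
  st <- do.call(rbind, rows)
  st$p_adj <- hochberg_adjust(st$p)
  st
}

config_hash <- function(config) {
  plain <- unclass(config)
  plain$out_dir <- NULL                 # fingerprint the science, not paths
  plain$synth <- unclass(plain$synth)
  plain$detector <- unclass(plain$detector)
  js <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                         null = "null")
  # small rolling hash; stdlib-only fingerprint for the manifest
  b <- utf8ToInt(as.character(js))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

write_bundle <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df) || !is.data.frame(df)) return()
    df$run_hash <- out$manifest$config_hash
    utils::write.csv(df, file.path(config$out_dir, name),
                     row.names = FALSE)
  }
  wr(out$windows, "windows.csv")
  wr(out$tones, "tones.csv")
  wr(out$dynamics, "hilbert_dynamics.csv")
  wr(out$swa, "swa_subwindows.csv")
  wr(out$spindles, "spindles.csv")
  wr(out$spindle_prob, "spindle_probability.csv")
  wr(out$baseline_pairs, "baseline_pairs.csv")
  wr(out$hrv, "hrv.csv")
  wr(out$ihr_change, "ihr_change.csv")
  wr(out$stats, "stats.csv")
  if (!is.null(out$hypnogram))
    wr(data.frame(epoch = seq_along(out$hypnogram$stages),
                  stage = out$hypnogram$stages), "hypnogram.csv")
  jsonlite::write_json(out$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(NULL)
}
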