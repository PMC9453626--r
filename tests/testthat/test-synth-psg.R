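# Synthetic polysomnography generator: hypnogram plausibility, spectral
# content by stage, event bookkeeping, injection contracts, RR series.

test_that("generated hypnogram has the right size, determinism and NREM runs", {
  hyp <- generate_hypnogram(8, seed = 1)
  expect_equal(length(hyp$stages), 8 * 3600 / 20)
  expect_identical(hyp$stages, generate_hypnogram(8, seed = 1)$stages)
  expect_false(identical(hyp$stages,
                         generate_hypnogram(8, seed = 2)$stages))
  # at least one continuous N2/N3 run of >= 30 epochs (10 min)
  r <- rle(hyp$stages %in% c("N2", "N3"))
  expect_gte(max(r$lengths[r$values]), 30)
  # all stages from the fixed vocabulary; REM appears later, not first
  expect_true(all(hyp$stages %in% c("WAKE", "N1", "N2", "N3", "REM")))
  expect_error(generate_hypnogram(0), "positive")
})

test_that("stage vocabulary is enforced", {
  expect_error(hypnogram(c("N2", "N9")), "unknown")
  expect_error(hypnogram(character(0)), "empty")
})

test_that("N3 EEG concentrates power in the slow-wave band", {
  hyp <- hypnogram(rep("N3", 30))
  p <- synth_params(seed = 7, movement_rate = 0, spindle_rate = 0)
  gen <- generate_eeg(hyp, p)
  ps <- welch_psd(gen$recording$signals$Fz, 500)
  expect_gte(psd_band_power(ps, c(0.5, 2)) / psd_band_power(ps, c(20, 30)),
             10)
})

test_that("zero amplitudes give pure noise and empty ground truth", {
  hyp <- hypnogram(rep("N3", 9))
  p <- synth_params(seed = 8, movement_rate = 0, spindle_rate = 0,
                    so_amp_by_stage = c(WAKE = 0, N1 = 0, N2 = 0, N3 = 0,
                                        REM = 0))
  gen <- generate_eeg(hyp, p)
  expect_equal(nrow(gen$truth$spindles), 0)
  expect_equal(nrow(gen$truth$movements), 0)
  # 1/f-ish: low band carries more power than an equal-width high band
  ps <- welch_psd(gen$recording$signals$Fz, 500)
  expect_gt(psd_band_power(ps, c(1, 5)), psd_band_power(ps, c(30, 34)))
})

test_that("REM nights carry anti-correlated EOG deflections", {
  hyp <- hypnogram(rep("REM", 30))
  p <- synth_params(seed = 9, movement_rate = 0)
  gen <- generate_eeg(hyp, p)
  defl <- gen$truth$eog_deflections
  expect_gt(nrow(defl), 10)
  e1 <- gen$recording$signals$EOG1
  e2 <- gen$recording$signals$EOG2
  r <- vapply(seq_len(nrow(defl)), function(i) {
    idx <- seq(round(defl$start[i] * 500) + 1,
               round((defl$start[i] + defl$duration[i]) * 500))
    stats::cor(e1[idx], e2[idx])
  }, numeric(1))
  expect_lt(stats::median(r), 0)
})

test_that("seed determinism gives bit-identical recordings", {
  hyp <- hypnogram(rep(c("N2", "N3"), 8))
  p <- synth_params(seed = 10)
  g1 <- generate_eeg(hyp, p)
  g2 <- generate_eeg(hyp, p)
  expect_identical(g1$recording$signals, g2$recording$signals)
  expect_identical(g1$truth$spindles, g2$truth$spindles)
})

test_that("spindle ground truth counts injected bursts exactly", {
  hyp <- hypnogram(rep("N2", 30))
  p <- synth_params(seed = 11, movement_rate = 0, spindle_rate = 4)
  gen <- generate_eeg(hyp, p)
  ev <- gen$truth$spindles
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$duration >= 0.5 & ev$duration <= 2))
  expect_true(all(ev$start >= 0 & ev$start + ev$duration <= hyp$duration))
  expect_true(all(ev$freq >= 10 & ev$freq <= 16))
})

test_that("stimulus-response injection honours its contracts", {
  f <- n2_quiet()
  w <- stim_windows(c("ISI1_High", "SHAM", "ISI1_High"),
                    c(100, 200, 300))
  # zero gain: identity
  p0 <- f$params
  p0$stim_response$peak_gain <- 0
  out0 <- inject_stim_response(f$recording, w, p0, f$truth)
  expect_identical(out0$recording$signals$Fz, f$recording$signals$Fz)
  # positive gain: SHAM windows and out-of-window samples bit-identical
  out <- inject_stim_response(f$recording, w, f$params, f$truth)
  x0 <- f$recording$signals$Fz
  x1 <- out$recording$signals$Fz
  sham_idx <- seq(200 * 500 + 1, 220 * 500)
  expect_identical(x1[sham_idx], x0[sham_idx])
  gap_idx <- seq(140 * 500, 180 * 500)
  expect_identical(x1[gap_idx], x0[gap_idx])
  on_idx <- seq(100 * 500 + 2, 110 * 500)
  expect_false(identical(x1[on_idx], x0[on_idx]))
  expect_error(
    inject_stim_response(f$recording, stim_windows("UP", f$recording$duration),
                         f$params),
    "outside")
})

test_that("injected gain doubles the slow-wave envelope early in ON", {
  f <- n2_quiet()
  w <- stim_windows(rep(c("UP", "SHAM"), 10), 60 + (0:19) * 40)
  p <- f$params
  p$stim_response <- list(peak_gain = 1.0, peak_latency = 0.5,
                          decay_tau = 3)
  out <- inject_stim_response(f$recording, w, p, f$truth)
  env <- band_envelope(out$recording$signals$Fz, 500, c(0.5, 2))
  up <- w[w$condition == "UP", ]
  early <- unlist(lapply(up$on_start, function(t0)
    env[seq(round((t0 + 0.4) * 500), round((t0 + 1.6) * 500))]))
  bg <- unlist(lapply(up$on_start, function(t0)
    env[seq(round((t0 + 15) * 500), round((t0 + 19) * 500))]))
  expect_gt(mean(early) / mean(bg), 1.6)
  expect_lt(mean(early) / mean(bg), 2.4)
})

test_that("RR generation reproduces requested rates and kernel direction", {
  no_w <- stim_windows(character(0), numeric(0))
  flat <- list(base_hr = 60, rsa_amp = 0, rsa_freq = 0.25, drift_amp = 0,
               drift_freq = 0.005, rr_noise_ms = 0,
               ihr_kernel = list(accel_ms = 0, accel_dur_s = 4,
                                 decel_ms = 0, decel_dur_s = 8),
               ecg_noise_mv = 0.02)
  p <- synth_params(seed = 12, cardiac = flat)
  rrg <- generate_rr(120, no_w, p)
  expect_true(all(abs(rrg$rr$rr - 1000) < 1e-9))
  flat2 <- flat; flat2$base_hr <- 120
  rrg2 <- generate_rr(120, no_w, synth_params(seed = 12, cardiac = flat2))
  expect_true(all(abs(rrg2$rr$rr - 500) < 1e-9))
  # deceleration kernel lengthens RR inside stimulation windows
  w <- stim_windows(rep(c("UP", "SHAM"), 20), 30 + (0:39) * 25)
  k <- flat; k$ihr_kernel$decel_ms <- 20
  rrk <- generate_rr(1100, w, synth_params(seed = 12, cardiac = k))
  rr <- rrk$rr
  in_cond <- function(cond) {
    w2 <- w[w$condition == cond, ]
    sel <- rowSums(outer(rr$r_times[-1], w2$on_start, ">=") &
                     outer(rr$r_times[-1], w2$on_start + 20, "<")) > 0
    mean(rr$rr[sel])
  }
  expect_gt(in_cond("UP"), in_cond("SHAM"))
  # impossible kernel rejected
  bad <- flat; bad$ihr_kernel$accel_ms <- 2000
  expect_error(generate_rr(60, no_w, synth_params(seed = 1, cardiac = bad)),
               "non-positive")
})

test_that("rendered ECG supports near-perfect peak recovery", {
  p <- synth_params(seed = 13)
  rrg <- generate_rr(300, stim_windows(character(0), numeric(0)), p)
  det <- detect_r_peaks(rrg$ecg$signals$ECG, 500)
  d <- vapply(rrg$truth$r_times,
              function(t) min(abs(det$r_times - t)), numeric(1))
  expect_gte(mean(d < 0.010), 0.99)
})
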