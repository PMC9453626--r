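# EEG metric chain: Welch spectra, percentage change, Hilbert dynamics,
# sub-window SWA, spindles, probability distribution, baseline pairing,
# early/late split.

test_that("welch_psd satisfies Parseval and quadratic scaling", {
  fs <- 200
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  ps <- welch_psd(x, fs)
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(df, 0.25)
  expect_equal(sum(ps$power) * df, 0.5, tolerance = 0.05)
  # energy concentrated at 2 Hz
  expect_gt(ps$power[ps$freq == 2], 0.9 * max(ps$power))
  expect_true(all(welch_psd(numeric(fs * 8), fs)$power == 0))
  ps4 <- welch_psd(2 * x, fs)
  expect_equal(ps4$power[-1] / pmax(ps$power[-1], 1e-300),
               rep(4, nrow(ps) - 1), tolerance = 1e-6)
  expect_error(welch_psd(numeric(100), fs), "shorter")
})

test_that("normalized spectra sum to one below 30 Hz", {
  set.seed(31)
  ps <- welch_psd(rnorm(200 * 20), 200, normalize = "cumulative_to_30Hz")
  expect_equal(sum(ps$power[ps$freq <= 30]), 1, tolerance = 1e-9)
})

test_that("percentage PSD change handles the trivial algebra and zeros", {
  set.seed(32)
  sham <- welch_psd(rnorm(200 * 12), 200)
  same <- psd_percent_change(sham, sham)
  expect_true(all(same$pct_change[sham$power > 0] == 0))
  mod <- sham; mod$power <- sham$power * 1.5
  expect_equal(psd_percent_change(mod, sham)$pct_change[10], 50,
               tolerance = 1e-9)
  zero <- sham; zero$power <- 0
  expect_equal(psd_percent_change(zero, sham)$pct_change[sham$power > 0],
               rep(-100, sum(sham$power > 0)), tolerance = 1e-12)
  s0 <- sham; s0$power[5] <- 0
  expect_true(is.na(psd_percent_change(sham, s0)$pct_change[5]))
  expect_error(psd_percent_change(sham[1:10, ], sham), "match")
})

test_that("hilbert dynamics are flat when no response is injected", {
  f <- n2_quiet()
  w <- stim_windows(rep(c("UP", "SHAM"), 12), 60 + (0:23) * 23)
  dyn <- hilbert_dynamics(f$recording$signals$Fz, 500, w)
  d <- dyn[dyn$condition == "UP", ]
  # |mean| < 2*SEM at most time points: no systematic deviation beyond
  # the level noise of 12 windows (slow depth-of-sleep modulation makes
  # across-window levels correlated, so only a loose absolute bound holds)
  expect_gt(mean(abs(d$pct_change) < 2 * d$sem_pct * sqrt(2)), 0.8)
  expect_lt(abs(mean(d$pct_change)), 20)
})

test_that("injected early-decaying response shapes dynamics and SWA", {
  f <- n2_quiet()
  w <- stim_windows(rep(c("ISI1_High", "SHAM"), 15), 60 + (0:29) * 23)
  out <- inject_stim_response(f$recording, w, f$params, f$truth)
  x <- out$recording$signals$Fz
  dyn <- hilbert_dynamics(x, 500, w)
  d <- dyn[dyn$condition == "ISI1_High", ]
  pk_t <- d$time[which.max(d$pct_change)]
  expect_lt(pk_t, 3)
  expect_gt(max(d$pct_change), 30)
  late_on <- mean(d$pct_change[d$time > 7 & d$time <= 10])
  expect_lt(late_on, max(d$pct_change) / 2)
  # sub-window SWA: ON1 exceeds ON2 for the injected condition
  sw <- swa_subwindows(x, 500, w[w$condition == "ISI1_High", ])
  expect_gt(mean(sw$swa[sw$sub == "ON1"]), mean(sw$swa[sw$sub == "ON2"]))
})

test_that("sub-window SWA is uniform for stationary signals", {
  set.seed(33)
  fs <- 200
  x <- bandpass(rnorm(fs * 120), fs, c(0.5, 2)) * 50
  w <- stim_windows(c("UP", "UP"), c(20, 60))
  sw <- swa_subwindows(x, fs, w)
  m <- tapply(sw$swa, sw$sub, mean)
  expect_lt(diff(range(m)) / mean(m), 1)
  # out-of-band SWA is near zero relative to in-band
  hi <- swa_subwindows(x, fs, w, band = c(20, 30))
  expect_lt(mean(hi$swa), mean(sw$swa) / 100)
})

test_that("a lone spindle burst is recovered with accurate onset", {
  set.seed(34)
  fs <- 200
  n <- fs * 300
  x <- bandpass(rnorm(n), fs, c(10, 16)) * 3
  me <- mean(band_envelope(x, fs, c(10, 16)))
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  u <- tt / 1
  envl <- ifelse(u < 0.25, 0.5 * (1 - cos(4 * pi * u)),
                 ifelse(u > 0.75, 0.5 * (1 - cos(4 * pi * (1 - u))), 1))
  burst <- 3 * me * envl * sin(2 * pi * 13 * tt)
  x[(150 * fs + 1):(151 * fs)] <- x[(150 * fs + 1):(151 * fs)] + burst
  ev <- detect_spindles(x, fs)
  near <- ev[abs(ev$start - 150) < 1, ]
  expect_equal(nrow(near), 1)
  expect_lt(abs(near$start - 150), 0.25)
  expect_equal(near$freq, 13, tolerance = 1)
  # same burst at 7x mean: rejected by the artifact upper bound
  x2 <- bandpass(rnorm(n), fs, c(10, 16)) * 3
  me2 <- mean(band_envelope(x2, fs, c(10, 16)))
  x2[(150 * fs + 1):(151 * fs)] <- x2[(150 * fs + 1):(151 * fs)] +
    7 * me2 * envl * sin(2 * pi * 13 * tt)
  ev2 <- detect_spindles(x2, fs)
  expect_equal(nrow(ev2[abs(ev2$start - 150) < 1, ]), 0)
  # all-zero input: no events
  expect_equal(nrow(detect_spindles(numeric(fs * 60), fs)), 0)
})

test_that("spindle probability counts window-bin occupancy correctly", {
  w <- stim_windows(c("UP", "SHAM", "UP", "UP"), c(0, 25, 50, 75))
  ev <- data.frame(start = c(3.1, 3.5, 60), duration = 1, freq = 13,
                   peak_env = 1)
  pr <- spindle_probability(ev, w)
  expect_equal(nrow(pr), 10)
  # two starts in the same bin of window 1 still count once: 1/4
  expect_equal(pr$probability[pr$bin_start == 2], 0.25)
  # window 3 has a spindle at rel 10 s -> bin [10,12)
  expect_equal(pr$probability[pr$bin_start == 10], 0.25)
  expect_equal(sum(pr$probability), 0.5)
  expect_error(spindle_probability(ev, w[0, ]), "no valid")
})

test_that("baseline pairing keeps only windows with a nearby SHAM", {
  f <- n2_quiet()
  x <- f$recording$signals$Fz
  w <- stim_windows(c("ISI1_High", "SHAM", "ISI1_High"),
                    c(100, 150, 700))
  pairs <- baseline_swa_pairs(x, 500, w)
  expect_equal(pairs$window_id, 1)       # 700 s window has no SHAM in 5 min
  expect_equal(pairs$sham_id, 2)
  expect_gt(pairs$baseline_swa, 0)
  # swapping the roles of the two windows inverts the relative change
  p2 <- baseline_swa_pairs(x, 500, stim_windows(c("ISI1_High", "SHAM"),
                                                c(100, 150)))
  p3 <- baseline_swa_pairs(x, 500, stim_windows(c("SHAM", "ISI1_High"),
                                                c(100, 150)))
  expect_equal(p2$pct_change / 100 + 1, 1 / (p3$pct_change / 100 + 1),
               tolerance = 1e-9)
})

test_that("early/late split uses the half-open 4 h convention", {
  w <- stim_windows(rep("UP", 4), c(0, 3600, 4 * 3600, 6 * 3600))
  sp <- split_early_late(w)
  expect_equal(sp$early$on_start, c(0, 3600))
  expect_equal(sp$late$on_start, c(4 * 3600, 6 * 3600))
  # all in hour 1: late empty
  sp2 <- split_early_late(stim_windows(rep("UP", 3), c(0, 100, 200)))
  expect_equal(nrow(sp2$late), 0)
  # uniform windows over 7 h: counts about 4:3
  w3 <- stim_windows(rep("UP", 70), seq(0, 7 * 3600 - 60, length.out = 70))
  sp3 <- split_early_late(w3)
  expect_equal(nrow(sp3$early) / nrow(w3), 4 / 7, tolerance = 0.05)
  expect_error(split_early_late(w[0, ]), "no stimulation")
})

test_that("window validity respects stages and movement artifacts", {
  hyp <- hypnogram(c(rep("N2", 10), rep("REM", 5), rep("N3", 10)))
  w <- stim_windows(c("UP", "UP", "UP"), c(40, 190, 310))
  mv <- data.frame(start = 315, duration = 1)
  out <- mark_valid_windows(w, hyp, mv)
  expect_equal(out$valid, c(TRUE, FALSE, FALSE))
  out2 <- mark_valid_windows(w, hyp, NULL)
  expect_equal(out2$valid, c(TRUE, FALSE, TRUE))
})

test_that("baseline SWA predicts the SWA enhancement across subjects", {
  # several synthetic nights ("subjects"): within each, windows with more
  # pre-stimulus SWA show a larger first-5 s enhancement relative to their
  # paired SHAM, which rmcorr must recover as a positive common slope
  rows <- list()
  for (subj in 1:6) {
    hyp <- hypnogram(rep("N3", 110))
    p <- synth_params(seed = 300 + subj, movement_rate = 0,
                      spindle_rate = 0,
                      stim_response = list(peak_gain = 0.8,
                                           peak_latency = 0.5,
                                           decay_tau = 3,
                                           baseline_coupling = 1))
    gen <- generate_eeg(hyp, p)
    set.seed(400 + subj)                 # jittered spacing decouples the
    starts <- 30 + cumsum(c(0, runif(87, 21, 27)))  # infraslow modulation
    w <- stim_windows(rep(c("ISI1_High", "SHAM"), 44), starts)
    inj <- inject_stim_response(gen$recording, w, p, gen$truth)
    pairs <- baseline_swa_pairs(inj$recording$signals$Fz, 500, w)
    pairs$subject <- subj
    rows[[subj]] <- pairs
  }
  all_pairs <- do.call(rbind, rows)
  expect_gt(nrow(all_pairs), 120)
  r <- rmcorr(all_pairs$subject, all_pairs$baseline_swa,
              all_pairs$pct_change)
  expect_gt(r$r_rm, 0)
  expect_lt(r$p, 0.05)
})
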