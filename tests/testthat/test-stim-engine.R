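# Closed-loop engine: causal power streams, gates, eligibility state
# machine, PLL phase tracking, sequencing, scheduling, tone plans, audio.

cfg <- detector_config()

test_that("band power stream separates in-band from out-of-band tones", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 3 * t)
  inb <- band_power_stream(x, fs, c(2, 4), cfg)
  outb <- band_power_stream(x, fs, c(20, 30), cfg)
  late <- inb$time > 10
  expect_gt(mean(inb$power[late]) / mean(outb$power[late] + 1e-15), 100)
  expect_true(all(band_power_stream(numeric(6000), fs, c(2, 4),
                                    cfg)$power == 0))
  expect_error(band_power_stream(x, fs, c(90, 110), cfg), "Nyquist")
})

test_that("band power scales quadratically with amplitude", {
  set.seed(3)
  x <- rnorm(200 * 60)
  p1 <- band_power_stream(x, 200, c(2, 4), cfg)
  p2 <- band_power_stream(2 * x, 200, c(2, 4), cfg)
  late <- p1$time > 10
  expect_equal(mean(p2$power[late]) / mean(p1$power[late]), 4,
               tolerance = 1e-9)
})

test_that("band power stream is causal", {
  set.seed(4)
  x <- rnorm(200 * 30)
  p1 <- band_power_stream(x, 200, c(2, 4), cfg)
  x2 <- x
  x2[(200 * 20):(200 * 30)] <- x2[(200 * 20):(200 * 30)] + 50
  p2 <- band_power_stream(x2, 200, c(2, 4), cfg)
  pre <- p1$time < 19.9
  expect_identical(p1$power[pre], p2$power[pre])
})

test_that("beta threshold calibration follows mean + k*SD", {
  expect_equal(calibrate_beta_threshold(rep(3, 100), 2), 3)
  v <- 1:100
  expect_equal(calibrate_beta_threshold(v, 2), mean(v) + 2 * sd(v))
  expect_error(calibrate_beta_threshold(numeric(0)), "pending")
})

test_that("EOG gate closes on anti-correlation only", {
  fs <- 200
  set.seed(5)
  e1 <- bandpass(rnorm(fs * 60), fs, c(0.3, 5))
  anti <- eog_anticorr_gate(e1, -e1, fs, cfg)
  late <- anti$time > 5
  expect_true(all(anti$r[late] < -0.99))
  expect_false(any(anti$open[late]))
  same <- eog_anticorr_gate(e1, e1, fs, cfg)
  expect_true(all(same$open[late]))
  # independent noise: gate open in >= 95% of windows
  e2 <- bandpass(rnorm(fs * 60), fs, c(0.3, 5))
  ind <- eog_anticorr_gate(e1, e2, fs, cfg)
  expect_gte(mean(ind$open[late]), 0.95)
  # constant segments: correlation treated as 0, gate open
  z <- eog_anticorr_gate(numeric(fs * 10), numeric(fs * 10), fs, cfg)
  expect_true(all(z$r == 0) && all(z$open))
})

test_that("movement gate closes for the 10 s holdoff", {
  fs <- 100
  x <- numeric(fs * 200)
  x[100 * fs] <- 500
  g <- movement_gate(x, fs, cfg)
  closed <- g$time[!g$open]
  expect_gte(min(closed), 100)
  expect_lte(max(closed), 110.01)
  expect_true(all(!g$open[g$time > 100 & g$time <= 109.9]))
  # always below cut: open
  expect_true(all(movement_gate(numeric(fs * 30), fs, cfg)$open))
  # two spikes 5 s apart: closed until 10 s past the second
  x2 <- numeric(fs * 200)
  x2[100 * fs] <- 500; x2[105 * fs] <- 500
  g2 <- movement_gate(x2, fs, cfg)
  expect_true(all(!g2$open[g2$time > 100 & g2$time <= 114.9]))
  expect_true(all(g2$open[g2$time > 115.1]))
})

test_that("state machine waits 10 min first, 3 min after interruptions", {
  dt <- 0.5
  n <- 3600 / dt                 # one hour of steps
  ts <- seq(dt, by = dt, length.out = n)
  # clean NREM throughout except a wake interruption at 40-41 min
  delta <- rep(100, n); beta <- rep(1, n)
  wake <- ts > 2400 & ts <= 2460
  delta[wake] <- 1; beta[wake] <- 50
  sm <- nrem_state_machine(data.frame(time = ts, power = delta),
                           data.frame(time = ts, power = beta), cfg = cfg)
  el <- ts[sm$steps$eligible]
  expect_equal(min(el), 600, tolerance = dt)
  expect_false(any(el > 2400 & el < 2460 + 180 - dt / 2))
  expect_equal(min(el[el > 2460]), 2460 + 180, tolerance = 2 * dt)
  # REM-like: EOG gate closed throughout -> never eligible
  sm2 <- nrem_state_machine(data.frame(time = ts, power = delta),
                            data.frame(time = ts, power = beta),
                            eog_open = rep(FALSE, n), cfg = cfg)
  expect_false(any(sm2$steps$eligible))
})

test_that("beta excursions above the calibrated threshold halt eligibility", {
  dt <- 0.5
  n <- 2400 / dt
  ts <- seq(dt, by = dt, length.out = n)
  set.seed(6)
  delta <- rep(100, n)
  beta <- pmax(rnorm(n, 1, 0.1), 0.01)
  spike <- ts > 700 & ts <= 710
  beta[spike] <- 10
  sm <- nrem_state_machine(data.frame(time = ts, power = delta),
                           data.frame(time = ts, power = beta), cfg = cfg)
  expect_false(any(sm$steps$eligible[spike]))
  expect_true(any(sm$steps$eligible[ts > 720]))
})

test_that("PLL locks and delivers both phase targets on the clean preset", {
  f <- sine_preset()
  x <- f$recording$signals$Fz
  for (targ in c(50, 230)) {
    res <- pll_delivery_phases(x, 500, targ, cfg)
    expect_gt(res$n, 300)
    expect_lt(abs(ang_diff(res$circ_mean, targ)), 10)
    expect_lt(res$circ_sd, 20)
  }
})

test_that("PLL locks on an off-frequency slow oscillation", {
  set.seed(7)
  fs <- 500
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  x <- 80 * sin(2 * pi * 0.8 * t) + rnorm(length(t), 0, 8)
  res <- pll_delivery_phases(x, fs, 50, cfg)
  expect_gt(res$n, 100)
  expect_lt(res$circ_sd, 20)
})

test_that("PLL stays silent on zero input", {
  pll <- pll_run(numeric(60000), 100, cfg)
  expect_false(any(pll$locked))
  expect_length(phase_triggers(pll, 50), 0)
})

test_that("single-sample pll_step agrees with the vectorised run", {
  set.seed(8)
  x <- 50 * sin(2 * pi * seq(0, 30, by = 0.01)) + rnorm(3001, 0, 5)
  run <- pll_run(x, 100, cfg)
  st <- pll_init(cfg)
  theta <- numeric(length(x))
  for (i in seq_along(x)) {
    st <- pll_step(x[i], st, 0.01)
    theta[i] <- st$theta
  }
  expect_equal(theta, run$theta, tolerance = 1e-12)
  expect_equal(st$locked, run$locked[length(x)])
})

test_that("condition sequencing is balanced permutation blocks", {
  conds <- c("UP", "DOWN", "ISI1_High", "ENVELOPE", "BINAURAL_BEATS",
             "SHAM")
  nxt <- sequence_conditions(conds, seed = 3)
  draws <- vapply(1:60, function(i) nxt(), character(1))
  for (b in split(draws, rep(1:10, each = 6)))
    expect_setequal(b, conds)
  # determinism
  nxt2 <- sequence_conditions(conds, seed = 3)
  expect_identical(vapply(1:60, function(i) nxt2(), character(1)), draws)
  # single condition: constant stream
  one <- sequence_conditions("SHAM", seed = 1)
  expect_identical(vapply(1:5, function(i) one(), character(1)),
                   rep("SHAM", 5))
  expect_error(sequence_conditions(character(0)), "at least one")
})

test_that("scheduler respects eligibility, spacing and SHAM silence", {
  conds <- default_conditions()
  seqr <- sequence_conditions(names(conds), seed = 2)
  elig <- data.frame(time = seq(0.5, 900, by = 0.5), eligible = TRUE)
  trig <- list("50" = seq(5, 895, by = 1.01),
               "230" = seq(5.5, 895, by = 1.01))
  w <- schedule_windows(elig, trig, seqr, conds, duration = 900)
  expect_gt(nrow(w), 20)
  expect_true(all(diff(w$on_start) >= 20 - 1e-9))
  counts <- table(factor(w$condition, levels = names(conds)))
  expect_lte(diff(range(counts)), 1)
  # never eligible: empty schedule
  seqr2 <- sequence_conditions(names(conds), seed = 2)
  elig0 <- data.frame(time = seq(0.5, 900, by = 0.5), eligible = FALSE)
  expect_equal(nrow(schedule_windows(elig0, trig, seqr2, conds, 900)), 0)
})

test_that("tone plans follow each condition's rule", {
  conds <- default_conditions(c("UP", "DOWN", "ISI1_High", "ISI1_Low",
                                "ISI1_Mod", "ENVELOPE", "BINAURAL_BEATS",
                                "SHAM"))
  w <- stim_windows("ISI1_Mod", 100)
  tn <- plan_tones(w[1, ], conds$ISI1_Mod)
  expect_equal(tn$time, 100 + 0:9)
  expect_equal(tn$volume_db,
               c(40, 40, 42.5, 42.5, 45, 45, 45, 45, 42.5, 42.5))
  # SHAM: silent
  expect_equal(nrow(plan_tones(stim_windows("SHAM", 100)[1, ],
                               conds$SHAM)), 0)
  # UP: one tone per trigger inside ON, boundary-crossing tone dropped
  trig <- c(99.5, 100.2, 101.3, 105.0, 109.99, 110.5)
  tu <- plan_tones(stim_windows("UP", 100)[1, ], conds$UP, trig)
  expect_equal(tu$time, c(100.2, 101.3, 105.0))
  # ENVELOPE: one 10 s event
  te <- plan_tones(stim_windows("ENVELOPE", 100)[1, ], conds$ENVELOPE)
  expect_equal(nrow(te), 1)
  expect_equal(te$duration_ms, 10000)
})

test_that("rendered audio matches the condition acoustics", {
  conds <- default_conditions(c("BINAURAL_BEATS", "UP", "SHAM"))
  fs <- 8000
  # binaural: spectral peaks at 400 and 401 Hz
  tb <- data.frame(window_id = 1, time = 0, duration_ms = 10000,
                   volume_db = 45)
  wav <- render_audio(tb, conds$BINAURAL_BEATS, fs, duration_s = 10)
  pk <- function(ch) {
    sp <- Mod(stats::fft(ch))[1:(length(ch) / 2)]
    (which.max(sp) - 1) / 10          # 10 s record -> 0.1 Hz resolution
  }
  expect_equal(pk(wav[, 1]), 400, tolerance = 0.2)
  expect_equal(pk(wav[, 2]), 401, tolerance = 0.2)
  # empty plan: silence
  expect_true(all(render_audio(tb[0, ], conds$SHAM, fs) == 0))
  # pink burst: ~ -3 dB/octave over 100-2000 Hz
  tp <- data.frame(window_id = 1, time = 0, duration_ms = 2000,
                   volume_db = 45)
  set.seed(9)
  wavp <- render_audio(tp, conds$UP, fs, duration_s = 2, seed = 9)
  ps <- welch_psd(wavp[, 1], fs, window_sec = 0.5)
  sel <- ps$freq >= 100 & ps$freq <= 2000 & ps$power > 0
  fit <- lm(10 * log10(ps$power[sel]) ~ log2(ps$freq[sel]))
  expect_equal(unname(coef(fit)[2]), -3, tolerance = 0.7)
})

test_that("full engine keeps windows sane on a synthetic night", {
  hyp <- generate_hypnogram(0.7, seed = 21)
  p <- synth_params(seed = 21)
  gen <- generate_eeg(hyp, p, store_so = FALSE)
  eng <- run_stim_engine(gen$recording, cfg, default_conditions(),
                         seed = 21)
  w <- eng$windows
  expect_gt(nrow(w), 10)
  o <- order(w$on_start)
  expect_true(all(diff(w$on_start[o]) >= 20 - 1e-9))
  counts <- table(w$condition)
  expect_lte(diff(range(counts)), 1)
  # tones inside their ON windows; SHAM has none
  for (i in seq_len(nrow(w))) {
    tw <- eng$tones[eng$tones$window_id == w$window_id[i], ]
    if (w$condition[i] == "SHAM") {
      expect_equal(nrow(tw), 0)
    } else if (nrow(tw)) {
      expect_true(all(tw$time >= w$on_start[i] - 1e-9))
      expect_true(all(tw$time + tw$duration_ms / 1000 <=
                        w$on_start[i] + 10 + 1e-9))
    }
  }
})
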