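# Shared fixtures, built once per test run and cached in a local
# environment.  All fixtures are generated in code under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), .fixtures)
  get(name, envir = .fixtures)
}

# 20 min of continuous N2 with spindles disabled (spindle-free background).
n2_quiet <- function() fixture("n2_quiet", function() {
  hyp <- hypnogram(rep("N2", 60))
  p <- synth_params(seed = 101, movement_rate = 0, spindle_rate = 0)
  c(generate_eeg(hyp, p), list(hyp = hyp, params = p))
})

# 10 min clean 1 Hz sinusoid slow-wave preset (N3), light noise.
sine_preset <- function() fixture("sine_preset", function() {
  hyp <- hypnogram(rep("N3", 30))
  p <- synth_params(seed = 102, so_preset = "sinusoid", movement_rate = 0,
                    spindle_rate = 0, noise_amp = 8,
                    delta_amp_by_stage = c(WAKE = 0, N1 = 0, N2 = 0,
                                           N3 = 0, REM = 0),
                    beta_amp_by_stage = c(WAKE = 0, N1 = 0, N2 = 0,
                                          N3 = 0, REM = 0))
  c(generate_eeg(hyp, p), list(hyp = hyp, params = p))
})

# Matching circular difference in degrees.
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
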