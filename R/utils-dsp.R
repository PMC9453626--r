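# Shared signal-processing primitives: analytic signal, band-pass helpers,
# seeded RNG scoping.  All time conventions: seconds from recording start,
# intervals half-open [start, end).

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector (real signal).
#' @return complex vector `x + i*H(x)`.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) > 1)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase in the sine convention
#'
#' Phase of a band-limited signal defined so that the signal is proportional
#' to `sin(phase)`: 0 deg at the positive-going zero crossing, 90 deg at the
#' positive peak, 270 deg at the trough.  Computed from the analytic signal.
#'
#' @param x numeric vector, band-limited.
#' @return phase in degrees in `[0, 360)`.
#' @export
instantaneous_phase <- function(x) {
  z <- analytic_signal(x)
  (Arg(z) * 180 / pi + 90) %% 360
}

#' Band-pass filter with zero phase distortion
#'
#' Forward-backward (two-pass) Butterworth filtering; used throughout the
#' offline analysis chain where causality is not required.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @param order filter order per pass (default 2; higher orders
#'   are numerically fragile at very low normalized frequencies).
#' @return filtered vector, same length.
#' @export
bandpass <- function(x, rate, band, order = 2) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[2] >= rate / 2)
    stop("band edge at or above Nyquist (", rate / 2, " Hz)")
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Envelope (Hilbert amplitude) of a band-limited signal
#'
#' @inheritParams bandpass
#' @return non-negative numeric vector.
#' @export
band_envelope <- function(x, rate, band, order = 2) {
  Mod(analytic_signal(bandpass(x, rate, band, order = order)))
}

# Mirror-pad x by npad samples on both ends (reduces filter edge transients
# on short segments).
mirror_pad <- function(x, npad) {
  npad <- min(npad, length(x) - 1)
  c(rev(x[2:(npad + 1)]), x, rev(x)[2:(npad + 1)])
}

# 1/f^alpha noise of length n, unit standard deviation, via spectral shaping.
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))           # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)             # two-sided frequency index
  W <- W * f^(-alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / stats::sd(x)
}
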