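# Analytic-signal magnitude (Hilbert envelope) via the FFT, padded to a
# fast length for speed.
hilbert_envelope <- function(x) {
  n0 <- length(x)
  n <- next_fast_n(n0)
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Carrier specification
#'
#' @param kind `"gaussian"` or `"low_noise"`.
#' @param f_lo,f_hi Band edges in Hz.
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param seed Integer seed; carriers are deterministic given the spec.
#' @param n_iterations Envelope-flattening iterations for low-noise noise
#'   (default 10).
#' @param rolloff Band skirt slope, dB/octave (default 12).
#' @return An object of class `carrier_spec`.
#' @export
carrier_spec <- function(kind = c("gaussian", "low_noise"), f_lo, f_hi,
                         duration, sample_rate = 44100, seed = 1L,
                         n_iterations = 10L, rolloff = 12) {
  kind <- match.arg(kind)
  if (!(f_lo < f_hi && f_hi <= sample_rate / 2))
    stop("need f_lo < f_hi <= Nyquist")
  if (duration <= 0) stop("duration must be positive")
  structure(list(kind = kind, f_lo = f_lo, f_hi = f_hi, duration = duration,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations), rolloff = rolloff),
            class = "carrier_spec")
}

#' Band-limited Gaussian noise carrier
#'
#' White Gaussian noise band-limited with [apply_hann_band()] and scaled to
#' unit RMS.  Deterministic given the spec's seed.
#'
#' @param spec A [carrier_spec()].
#' @return Numeric waveform with unit RMS.
#' @export
gaussian_band_noise <- function(spec) {
  stopifnot(inherits(spec, "carrier_spec"))
  n <- round(spec$duration * spec$sample_rate)
  x <- withr_seed(spec$seed, stats::rnorm(n))
  x <- apply_hann_band(x, spec$f_lo, spec$f_hi, spec$rolloff, spec$sample_rate)
  x / rms(x)
}

# Run expr under a local RNG state (restores the caller's .Random.seed).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Low-noise noise carrier
#'
#' Band-limited noise with minimal intrinsic envelope fluctuation, so that
#' imposed speech envelopes dominate the modulation the listener receives.
#' Constructed iteratively from a Gaussian band noise: each iteration divides
#' the waveform by its own Hilbert envelope (floored at 1e-6 of its maximum)
#' and re-band-limits the result.  The normalized envelope standard deviation
#' decreases across iterations; `n_iterations = 0` returns the Gaussian
#' starting noise.
#'
#' @param spec A [carrier_spec()] with `kind = "low_noise"`.
#' @return Numeric waveform with unit RMS, spectrum confined to the band.
#' @export
low_noise_noise <- function(spec) {
  stopifnot(inherits(spec, "carrier_spec"))
  if (spec$f_hi - spec$f_lo <= 0) stop("bandwidth must be positive")
  x <- gaussian_band_noise(spec)
  if (spec$n_iterations < 1L) return(x)
  n0 <- length(x)
  n <- next_fast_n(n0)
  x <- c(x, numeric(n - n0))
  freqs <- fft_freqs(n, spec$sample_rate)
  h <- band_transfer(freqs, spec$f_lo, spec$f_hi, spec$rolloff)
  hh <- numeric(n)
  if (n %% 2 == 0) { hh[c(1, n / 2 + 1)] <- 1; hh[2:(n / 2)] <- 2
  } else { hh[1] <- 1; hh[2:((n + 1) / 2)] <- 2 }
  for (i in seq_len(spec$n_iterations)) {
    env <- Mod(stats::fft(stats::fft(x) * hh, inverse = TRUE) / n)
    env <- pmax(env, 1e-6 * max(env))
    x <- apply_transfer(x / env, h)
  }
  x <- x[seq_len(n0)]
  x / rms(x)
}

#' Normalized zero-lag interaural correlation
#'
#' @param left,right Equal-length waveforms with nonzero energy.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
interaural_correlation <- function(left, right) {
  if (length(left) != length(right)) stop("waveforms must have equal length")
  el <- sum(left^2); er <- sum(right^2)
  if (el == 0 || er == 0) stop("zero-energy input")
  sum(left * right) / sqrt(el * er)
}

#' Derive a per-trial, per-ear, per-band carrier seed
#'
#' Deterministic hash mixing the schedule seed, trial id, ear and band index
#' so that every carrier in an experiment is reproducible yet the two ears
#' (and all bands) use statistically independent noise.  The hash is a
#' splitmix-style integer mix reduced modulo 2^31 - 1.
#'
#' @param schedule_seed Integer master seed.
#' @param trial_id Trial number.
#' @param ear `"left"` or `"right"`.
#' @param band Band index (1-based).
#' @return A positive integer seed < 2^31.
#' @export
carrier_seed <- function(schedule_seed, trial_id, ear = c("left", "right"),
                         band = 1L) {
  ear <- match.arg(ear)
  ear_code <- if (ear == "left") 1 else 2
  # mix in double precision; all intermediates stay below 2^53
  m <- 2147483647
  h <- (as.numeric(schedule_seed) %% m)
  for (v in c(as.numeric(trial_id), ear_code, as.numeric(band))) {
    h <- (h * 69069 + v * 362437 + 1013904223) %% m
    h <- (h * 40692) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
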