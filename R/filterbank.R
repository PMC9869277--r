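#' Greenwood frequency-position map
#'
#' Converts between fractional cochlear position and characteristic frequency
#' using the human Greenwood map \eqn{f = A (10^{a x} - k)} with the standard
#' human constants \eqn{A = 165.4}, \eqn{a = 2.1} (position expressed as a
#' fraction of cochlear length) and \eqn{k = 0.88}.
#'
#' @param x Cochlear position as a fraction of basilar-membrane length,
#'   in \[0, 1\] (0 = apex, 1 = base).
#' @param f Frequency in Hz, > 0.
#' @param A,a,k Greenwood constants; defaults are the standard human values.
#' @return `greenwood_frequency()` returns frequency in Hz;
#'   `greenwood_position()` returns the fractional position.
#' @examples
#' greenwood_frequency(0.5)
#' greenwood_position(greenwood_frequency(0.5))
#' @export
greenwood_frequency <- function(x, A = 165.4, a = 2.1, k = 0.88) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("cochlear position must lie in [0, 1]")
  A * (10^(a * x) - k)
}

#' @rdname greenwood_frequency
#' @export
greenwood_position <- function(f, A = 165.4, a = 2.1, k = 0.88) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequency must be positive")
  log10(f / A + k) / a
}

#' Filterbank specification
#'
#' Parameters of the analysis filterbank: `n_bands` bands spanning `f_low` to
#' `f_high` Hz, spaced over equal cochlear distance on the Greenwood map, with
#' skirts falling at `rolloff` dB/octave, and an envelope low-pass cutoff of
#' `env_cutoff` Hz.
#'
#' @param n_bands Number of analysis bands (default 16).
#' @param f_low,f_high Lower and upper frequency limit in Hz (defaults 250 and
#'   8000).
#' @param rolloff Skirt slope in dB per octave outside the band (default 12).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param env_cutoff Envelope low-pass cutoff in Hz (default 600).
#' @return An object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(n_bands = 16L, f_low = 250, f_high = 8000,
                            rolloff = 12, sample_rate = 44100,
                            env_cutoff = 600) {
  if (!(f_low > 0 && f_low < f_high && f_high < sample_rate / 2))
    stop("need 0 < f_low < f_high < sample_rate/2")
  if (n_bands < 1L) stop("n_bands must be >= 1")
  if (rolloff <= 0) stop("rolloff must be > 0")
  structure(list(n_bands = as.integer(n_bands), f_low = f_low, f_high = f_high,
                 rolloff = rolloff, sample_rate = sample_rate,
                 env_cutoff = env_cutoff),
            class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf("Filterbank: %d Greenwood-spaced bands, %g-%g Hz, %g dB/oct skirts, fs = %g Hz\n",
              x$n_bands, x$f_low, x$f_high, x$rolloff, x$sample_rate))
  invisible(x)
}

#' Band edges over equal cochlear distance
#'
#' Computes the `n_bands + 1` band-edge frequencies, equally spaced in
#' Greenwood position between `f_low` and `f_high`.
#'
#' @param spec A [filterbank_spec()].
#' @return Numeric vector of `n_bands + 1` strictly increasing edge
#'   frequencies in Hz; first equals `f_low`, last equals `f_high`.
#' @examples
#' compute_band_edges(filterbank_spec())
#' @export
compute_band_edges <- function(spec) {
  stopifnot(inherits(spec, "filterbank_spec"))
  x <- seq(greenwood_position(spec$f_low), greenwood_position(spec$f_high),
           length.out = spec$n_bands + 1L)
  edges <- greenwood_frequency(x)
  edges[1] <- spec$f_low
  edges[length(edges)] <- spec$f_high
  edges
}

# Real, non-negative zero-phase transfer function sampled on the two-sided FFT
# frequency grid: unity in [f_lo, f_hi], constant-slope skirts of `rolloff`
# dB per octave outside.  f_lo = 0 gives a pure low-pass.
band_transfer <- function(freqs, f_lo, f_hi, rolloff) {
  h <- numeric(length(freqs))
  inside <- freqs >= f_lo & freqs <= f_hi
  h[inside] <- 1
  above <- freqs > f_hi
  h[above] <- 10^(-(rolloff / 20) * log2(freqs[above] / f_hi))
  if (f_lo > 0) {
    below <- freqs < f_lo & freqs > 0
    h[below] <- 10^(-(rolloff / 20) * log2(f_lo / freqs[below]))
    # DC is infinitely many octaves below the edge
    h[freqs == 0] <- 0
  } else {
    h[freqs == 0] <- 1
  }
  h
}

# Two-sided frequency axis (Hz, folded magnitude) for an N-point FFT.
fft_freqs <- function(n, sample_rate) {
  f <- (seq_len(n) - 1) / n * sample_rate
  idx <- f > sample_rate / 2
  f[idx] <- sample_rate - f[idx]
  f
}

# Multiply a real signal's spectrum by a real even transfer function.
apply_transfer <- function(signal, transfer) {
  n <- length(signal)
  Re(stats::fft(stats::fft(signal) * transfer, inverse = TRUE)) / n
}

# Smallest 7-smooth integer >= n.  stats::fft is O(n^2) for lengths with
# large prime factors, so spectral ops zero-pad to a fast length and trim.
next_fast_n <- function(n) {
  if (n <= 2) return(n)
  repeat {
    m <- n
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# Zero-pad to a fast FFT length, filter with the transfer built by
# make_h(freqs), trim back to the original length.
spectral_filter <- function(signal, sample_rate, make_h) {
  n <- length(signal)
  np <- next_fast_n(n)
  x <- if (np > n) c(signal, numeric(np - n)) else signal
  h <- make_h(fft_freqs(np, sample_rate))
  apply_transfer(x, h)[seq_len(n)]
}

#' Zero-phase spectral band-pass (Hann-band style)
#'
#' Filters a waveform by multiplying its whole-signal spectrum by a real,
#' non-negative transfer function that is unity inside \[`f_lo`, `f_hi`\] and
#' falls at `rolloff` dB per octave outside the edges (constant slope in
#' log-frequency).  The filter is zero phase and exactly linear.
#'
#' @param signal Numeric waveform.
#' @param f_lo,f_hi Band edges in Hz; `f_lo = 0` gives a low-pass.
#' @param rolloff Skirt slope, dB/octave (default 12).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return Filtered waveform of the same length.
#' @export
apply_hann_band <- function(signal, f_lo, f_hi, rolloff = 12,
                            sample_rate = 44100) {
  if (length(signal) == 0) stop("signal is empty")
  if (f_lo >= f_hi) stop("need f_lo < f_hi")
  if (f_hi > sample_rate / 2) stop("band extends beyond the Nyquist frequency")
  spectral_filter(signal, sample_rate,
                  function(freqs) band_transfer(freqs, f_lo, f_hi, rolloff))
}

#' Temporal-envelope extraction
#'
#' Half-wave rectifies a band-limited waveform and low-passes the result with
#' the same spectral machinery used for band-pass filtering (a 0 to
#' `env_cutoff` Hz band with 12 dB/octave roll-off).  Negative residuals from
#' filter ringing are clipped to zero, so the envelope is non-negative.
#'
#' @param band Numeric waveform (one analysis band).
#' @param env_cutoff Low-pass cutoff in Hz (default 600).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return An object of class `envelope`: list with `samples` (non-negative
#'   linear amplitudes) and `sample_rate`.
#' @export
extract_envelope <- function(band, env_cutoff = 600, sample_rate = 44100) {
  if (length(band) == 0) stop("band is empty")
  rectified <- pmax(band, 0)
  env <- pmax(spectral_filter(rectified, sample_rate, function(freqs)
    band_transfer(freqs, 0, env_cutoff, 12)), 0)
  structure(list(samples = env, sample_rate = sample_rate), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("Envelope: %d samples at %g Hz, peak %.4g\n",
              length(x$samples), x$sample_rate, max(x$samples)))
  invisible(x)
}

#' Root-mean-square amplitude
#'
#' @param signal Numeric waveform (non-empty).
#' @return `sqrt(mean(signal^2))`.
#' @export
rms <- function(signal) {
  if (length(signal) == 0) stop("signal is empty")
  sqrt(mean(signal^2))
}

# Split a signal into the spec's bands; returns list of band waveforms.
# The input spectrum is computed once on a padded fast length.
filterbank_analyze <- function(signal, spec) {
  edges <- compute_band_edges(spec)
  n <- length(signal)
  np <- next_fast_n(n)
  x <- if (np > n) c(signal, numeric(np - n)) else signal
  freqs <- fft_freqs(np, spec$sample_rate)
  X <- stats::fft(x)
  lapply(seq_len(spec$n_bands), function(b) {
    h <- band_transfer(freqs, edges[b], edges[b + 1L], spec$rolloff)
    (Re(stats::fft(X * h, inverse = TRUE)) / np)[seq_len(n)]
  })
}
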