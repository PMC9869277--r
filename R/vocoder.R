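#' Seeded pink noise
#'
#' Gaussian noise spectrally shaped to a 1/f power spectral density (-3
#' dB/octave) from 20 Hz up to the Nyquist frequency (flat below 20 Hz, DC
#' removed), scaled to unit RMS.  Used as the level-calibration reference.
#'
#' @param duration Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param seed Integer seed.
#' @return Numeric waveform with unit RMS.
#' @export
pink_noise <- function(duration, sample_rate = 44100, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * sample_rate)
  x <- withr_seed(as.integer(seed), stats::rnorm(n))
  y <- spectral_filter(x, sample_rate, function(freqs) {
    shape <- 1 / sqrt(pmax(freqs, 20))
    shape[freqs == 0] <- 0
    shape
  })
  y / rms(y)
}

# IEC 61672 A-weighting magnitude in dB at frequency f (Hz).
a_weight_db <- function(f) {
  f2 <- f^2
  ra <- (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  20 * log10(ra) + 2.00
}

#' A-weighting filter
#'
#' Applies the standard A-weighting magnitude response (IEC 61672 analog
#' prototype, sampled on the FFT grid, zero phase) to a waveform.  Gain at
#' 1 kHz is 0 dB to within 0.1 dB.
#'
#' @param signal Numeric waveform.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return Weighted waveform of the same length.
#' @export
a_weight <- function(signal, sample_rate = 44100) {
  if (length(signal) == 0) stop("signal is empty")
  spectral_filter(signal, sample_rate, function(freqs) {
    h <- numeric(length(freqs))
    nz <- freqs > 0
    h[nz] <- 10^(a_weight_db(freqs[nz]) / 20)
    h
  })
}

#' Level reference for stimulus normalization
#'
#' Digital level calibration plus target: stimuli are normalized so their
#' A-weighted level equals that of pink noise presented at `target_db_a`
#' dB(A).  The calibration constant maps digital full scale to SPL: a
#' full-scale sine (RMS \eqn{1/\sqrt{2}}) corresponds to
#' `calibration_db_fs` dB SPL (default 100), so absolute playback level is a
#' configuration property and only relative levels matter internally.
#'
#' @param target_db_a Target level in dB(A) (default 65).
#' @param calibration_db_fs SPL of a digital full-scale sine (default 100).
#' @return Object of class `level_reference`.
#' @export
level_reference <- function(target_db_a = 65, calibration_db_fs = 100) {
  structure(list(target_db_a = target_db_a,
                 calibration_db_fs = calibration_db_fs,
                 reference_kind = "pink"),
            class = "level_reference")
}

# A-weighted level of a waveform in dB(A) under the calibration.
a_weighted_level <- function(signal, ref, sample_rate = 44100) {
  ref$calibration_db_fs +
    20 * log10(rms(a_weight(signal, sample_rate)) / (1 / sqrt(2)))
}

#' Render the pink-noise reference at the target level
#'
#' @param ref A [level_reference()].
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Pink-noise waveform whose A-weighted level equals
#'   `ref$target_db_a`.
#' @export
reference_noise <- function(ref, duration, sample_rate = 44100, seed = 1L) {
  stopifnot(inherits(ref, "level_reference"))
  p <- pink_noise(duration, sample_rate, seed)
  p * 10^((ref$target_db_a - a_weighted_level(p, ref, sample_rate)) / 20)
}

#' Normalize a waveform to the A-weighted reference level
#'
#' Scales `signal` so that its A-weighted RMS equals that of the pink-noise
#' reference rendered at the target dB(A) under the calibration constant.
#' Scale invariant: doubling the input amplitude yields the same output.
#'
#' @param signal Numeric waveform with nonzero energy.
#' @param ref A [level_reference()] (default `level_reference()`).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return Scaled waveform.
#' @export
normalize_to_reference <- function(signal, ref = level_reference(),
                                   sample_rate = 44100) {
  stopifnot(inherits(ref, "level_reference"))
  aw <- rms(a_weight(signal, sample_rate))
  if (aw == 0) stop("zero-energy signal cannot be normalized")
  target_rms <- (1 / sqrt(2)) *
    10^((ref$target_db_a - ref$calibration_db_fs) / 20)
  signal * (target_rms / aw)
}

#' Noise-vocode a monaural signal
#'
#' The full analysis-synthesis chain: the signal is split into the spec's
#' Greenwood-spaced bands, each band's temporal envelope is extracted
#' (half-wave rectification + low-pass), compressed in the dB domain to `dr`
#' percent of its original dynamic range, and multiplied onto a seeded
#' low-noise-noise carrier limited to the same band; the modulated carriers
#' are summed and the result is normalized to the A-weighted reference level.
#'
#' @param signal Monaural waveform at `spec$sample_rate` (non-empty).
#' @param dr Dynamic range retained, percent in \[0, 100\].
#' @param spec A [filterbank_spec()].
#' @param seed Integer seed for the carriers (deterministic output).
#' @param ref A [level_reference()].
#' @param ear,trial_id Mixed into the per-band carrier seeds via
#'   [carrier_seed()] so the two ears of a trial get independent carriers.
#' @param details If `TRUE`, attach per-band diagnostics (band edges,
#'   envelope dB range in and after compression).
#' @return Object of class `vocode_result`: list with `waveform` (same
#'   length as input), `dr_percent`, `seed`, and `per_band` (diagnostics
#'   data frame or `NULL`).
#' @export
vocode <- function(signal, dr, spec = filterbank_spec(), seed = 1L,
                   ref = level_reference(), ear = "left", trial_id = 0L,
                   details = FALSE) {
  if (length(signal) == 0) stop("signal is empty")
  if (dr < 0 || dr > 100) stop("dr must lie in [0, 100]")
  edges <- compute_band_edges(spec)
  bands <- filterbank_analyze(signal, spec)
  dur <- length(signal) / spec$sample_rate
  total <- numeric(length(signal))
  diag_rows <- if (details) vector("list", spec$n_bands) else NULL
  cspec <- compression_spec(dr, env_cutoff = spec$env_cutoff)
  for (b in seq_len(spec$n_bands)) {
    env <- extract_envelope(bands[[b]], spec$env_cutoff, spec$sample_rate)
    comp <- compress_envelope(env, cspec, details = TRUE)
    bseed <- carrier_seed(seed, trial_id, ear, b)
    carrier <- low_noise_noise(carrier_spec("low_noise", edges[b],
                                            edges[b + 1L], dur,
                                            spec$sample_rate, seed = bseed,
                                            rolloff = spec$rolloff))
    carrier <- carrier[seq_along(signal)]
    total <- total + carrier * comp$envelope$samples
    if (details)
      diag_rows[[b]] <- data.frame(band = b, f_lo = edges[b],
                                   f_hi = edges[b + 1L],
                                   range_in_db = comp$range_in_db,
                                   range_out_db = comp$range_post_rule_db)
  }
  out <- normalize_to_reference(total, ref, spec$sample_rate)
  structure(list(waveform = out, dr_percent = dr, seed = as.integer(seed),
                 per_band = if (details) do.call(rbind, diag_rows) else NULL),
            class = "vocode_result")
}

#' @export
print.vocode_result <- function(x, ...) {
  cat(sprintf("Vocoded waveform: %d samples, DR = %g%%, seed %d\n",
              length(x$waveform), x$dr_percent, x$seed))
  invisible(x)
}

#' Build one binaural (dichotic) stimulus
#'
#' Vocodes the two ears' signals independently — each ear gets its own
#' dynamic range and its own carrier seeds, so the interaural correlation of
#' the band carriers is zero in expectation.  `NA` dynamic range means the
#' unprocessed condition: the audio bypasses the vocoder but is still
#' normalized to the reference level.  Signals of unequal length are padded
#' with trailing silence to the longer one.
#'
#' @param left_sig,right_sig Monaural waveforms at `spec$sample_rate`.
#' @param dr_left,dr_right Per-ear dynamic range in percent, or `NA` for
#'   unprocessed.
#' @param spec A [filterbank_spec()].
#' @param trial_seed Integer seed; per-ear, per-band carrier seeds are
#'   derived from it with [carrier_seed()].
#' @param trial_id Trial number mixed into the carrier seeds.
#' @param ref A [level_reference()].
#' @return Two-column matrix (`left`, `right`) of equal-length waveforms,
#'   each normalized to the reference level.
#' @export
binaural_vocode <- function(left_sig, right_sig, dr_left, dr_right,
                            spec = filterbank_spec(), trial_seed = 1L,
                            trial_id = 0L, ref = level_reference()) {
  n <- max(length(left_sig), length(right_sig))
  pad <- function(x) c(x, numeric(n - length(x)))
  left_sig <- pad(left_sig); right_sig <- pad(right_sig)
  one_ear <- function(sig, dr, ear) {
    if (is.na(dr)) normalize_to_reference(sig, ref, spec$sample_rate)
    else vocode(sig, dr, spec, seed = trial_seed, ref = ref, ear = ear,
                trial_id = trial_id)$waveform
  }
  cbind(left = one_ear(left_sig, dr_left, "left"),
        right = one_ear(right_sig, dr_right, "right"))
}

#' Across-band envelope-energy profile
#'
#' RMS of each band's temporal envelope — a compact spectral signature used
#' to check that vowel identity survives vocoding (different-vowel words
#' keep more dissimilar profiles than same-vowel words).
#'
#' @param signal Monaural waveform.
#' @param spec A [filterbank_spec()].
#' @return Numeric vector of length `spec$n_bands`.
#' @export
band_energy_profile <- function(signal, spec = filterbank_spec()) {
  bands <- filterbank_analyze(signal, spec)
  vapply(bands, function(b)
    rms(extract_envelope(b, spec$env_cutoff, spec$sample_rate)$samples),
    numeric(1))
}

#' Cosine distance between two profiles
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return `1 - cos(a, b)`, in \[0, 2\].
#' @export
cosine_distance <- function(a, b) {
  1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
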