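#' Compression specification
#'
#' Parameters for dB-domain dynamic-range compression of a band envelope.
#' `dr_percent` is the percentage of the original dB range retained: 100
#' leaves the envelope unaltered, 0 flattens it to its maximum (only onsets
#' and offsets survive).  `max_db` is the fixed reference maximum (90 dB) the
#' envelope is pinned to before the samplewise compression rule is applied.
#'
#' @param dr_percent Dynamic range retained, percent in \[0, 100\].
#' @param max_db Reference maximum in dB (default 90).
#' @param epsilon Small positive linear offset added before the dB conversion;
#'   `NULL` (default) uses 1e-6 times the envelope maximum.
#' @param floor_threshold Linear amplitude below which samples are zeroed
#'   after decompression; `NULL` (default) reuses `epsilon`.
#' @param env_cutoff Low-pass cutoff in Hz for the final re-filtering
#'   (default 600).
#' @return An object of class `compression_spec`.
#' @export
compression_spec <- function(dr_percent, max_db = 90, epsilon = NULL,
                             floor_threshold = NULL, env_cutoff = 600) {
  if (!is.numeric(dr_percent) || dr_percent < 0 || dr_percent > 100)
    stop("dr_percent must lie in [0, 100]")
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  structure(list(dr_percent = dr_percent, max_db = max_db, epsilon = epsilon,
                 floor_threshold = floor_threshold, env_cutoff = env_cutoff),
            class = "compression_spec")
}

#' Samplewise dB-domain compression rule
#'
#' The core compression rule: each envelope value in dB is moved toward the
#' reference maximum by the fraction of the range being discarded,
#' \deqn{E_{compressed} = E_{full} + \frac{100 - DR}{100} (Max - E_{full}).}
#' Dips in the envelope are filled in; the dB range of any input set shrinks
#' to `dr` percent of its original span.  `dr = 100` is the identity and
#' `dr = 0` maps everything to `max_db`.
#'
#' @param e_full Envelope value(s) in dB.
#' @param dr Dynamic range retained, percent in \[0, 100\].
#' @param max_db Reference maximum in dB (default 90).
#' @return Compressed value(s) in dB.
#' @examples
#' compress_db_sample(60, dr = 60, max_db = 90)  # 72
#' @export
compress_db_sample <- function(e_full, dr, max_db = 90) {
  if (dr < 0 || dr > 100) stop("dr must lie in [0, 100]")
  e_full + (100 - dr) / 100 * (max_db - e_full)
}

#' Idealized compressed extremes
#'
#' Level-preserving description of what compression does to an envelope's
#' extremes: the dB range shrinks to `dr` percent of its original span while
#' the range midpoint is preserved, so the minimum rises and the maximum
#' falls symmetrically.  E.g. a 40 to 70 dB envelope compressed to 60 percent
#' spans 18 dB, from 46 to 64 dB.
#'
#' @param min_db,max_db_in Input envelope minimum and maximum in dB
#'   (`min_db < max_db_in`).
#' @param dr Dynamic range retained, percent.
#' @return Named numeric vector `c(new_min, new_max, new_range)` in dB.
#' @examples
#' compress_extremes(40, 70, dr = 60)  # 46, 64, 18
#' @export
compress_extremes <- function(min_db, max_db_in, dr) {
  if (min_db >= max_db_in) stop("need min_db < max_db_in")
  if (dr < 0 || dr > 100) stop("dr must lie in [0, 100]")
  new_range <- dr / 100 * (max_db_in - min_db)
  mid <- (min_db + max_db_in) / 2
  c(new_min = mid - new_range / 2, new_max = mid + new_range / 2,
    new_range = new_range)
}

#' Compress a band envelope's dynamic range in the dB domain
#'
#' Applies the full eleven-step procedure to a non-negative linear envelope:
#' (1) add a small positive offset, (2) convert to dB, (3) subtract the
#' maximum, (4) add 90 so the maximum sits at 90 dB, (5) fill in dips with the
#' samplewise compression rule ([compress_db_sample()]), (6) shift the maximum
#' back to its original level, (7) convert back to linear amplitude,
#' (8) remove the offset, (9) zero sub-threshold values, (10) low-pass
#' re-filter at `env_cutoff`, and (11) rescale to the original envelope RMS.
#'
#' Before re-filtering, the dB range of the envelope is exactly `dr` percent
#' of its input dB range, and sample ordering is preserved (for `dr > 0`).
#' The final output RMS matches the input RMS.  An all-zero envelope is
#' returned unchanged (degenerate case: it has no dynamic range to compress).
#'
#' @param env An [extract_envelope()] result, or a non-negative numeric
#'   vector (then `sample_rate` must be supplied).
#' @param spec A [compression_spec()].
#' @param sample_rate Sampling rate in Hz; taken from `env` when it is an
#'   `envelope` object.
#' @param details If `TRUE`, return a list with the compressed `envelope`
#'   plus diagnostics: `range_in_db`, `range_post_rule_db` (dB range right
#'   after the samplewise rule, before re-filtering), `rms_in`, `rms_out`.
#' @return An `envelope` object, or a diagnostics list when `details = TRUE`.
#' @export
compress_envelope <- function(env, spec, sample_rate = NULL, details = FALSE) {
  stopifnot(inherits(spec, "compression_spec"))
  if (inherits(env, "envelope")) {
    samples <- env$samples
    sample_rate <- env$sample_rate
  } else {
    samples <- as.numeric(env)
    if (is.null(sample_rate)) stop("sample_rate required for a bare vector")
  }
  if (any(samples < 0)) stop("envelope must be non-negative")

  peak <- max(samples)
  if (peak == 0) {
    out <- structure(list(samples = samples, sample_rate = sample_rate),
                     class = "envelope")
    if (details)
      return(list(envelope = out, range_in_db = 0, range_post_rule_db = 0,
                  rms_in = 0, rms_out = 0))
    return(out)
  }

  eps <- if (is.null(spec$epsilon)) 1e-6 * peak else spec$epsilon
  floor_thr <- if (is.null(spec$floor_threshold)) eps else spec$floor_threshold
  rms_in <- rms(samples)

  x <- samples + eps                          # (1)
  xdb <- 20 * log10(x)                        # (2)
  m <- max(xdb)
  xdb <- xdb - m + spec$max_db                # (3)+(4): maximum at 90 dB
  range_in <- diff(range(xdb))
  xdb <- compress_db_sample(xdb, spec$dr_percent, spec$max_db)  # (5)
  range_post <- diff(range(xdb))
  xdb <- xdb - spec$max_db + m                # (6)
  lin <- 10^(xdb / 20)                        # (7)
  lin <- lin - eps                            # (8)
  lin[lin < floor_thr] <- 0                   # (9)
  lin <- pmax(spectral_filter(lin, sample_rate, function(freqs)
    band_transfer(freqs, 0, spec$env_cutoff, 12)), 0)  # (10)
  rms_now <- rms(lin)
  if (rms_now > 0) lin <- lin * (rms_in / rms_now)  # (11)

  out <- structure(list(samples = lin, sample_rate = sample_rate),
                   class = "envelope")
  if (details)
    list(envelope = out, range_in_db = range_in,
         range_post_rule_db = range_post, rms_in = rms_in, rms_out = rms(lin))
  else out
}
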