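# Formant targets (Hz) per vowel: steady targets plus a diphthong drift for
# /ei/ and /ou/.  Textbook values for a male talker.
vowel_formants <- function(vowel) {
  switch(vowel,
    eh = list(start = c(550, 1800, 2500), end = c(550, 1800, 2500)),
    ei = list(start = c(550, 1900, 2600), end = c(400, 2200, 2800)),
    ou = list(start = c(500, 1000, 2400), end = c(450, 850, 2300)),
    stop("unknown vowel: ", vowel))
}

# Liquid onset locus: /l/ has a high F3, /r/ a markedly lowered F3.
liquid_locus <- function(liquid, vowel_start) {
  if (liquid == "l") c(360, 1100, 2900)
  else c(400, 1200, 1600)
}

#' Synthesize one pseudo-word token
#'
#' Source-filter synthesis of a monosyllable emulating the corpus structure:
#' a harmonic source near 102 Hz shaped by three formant resonances whose
#' trajectories realize the onset class — stop onsets get a short silence, a
#' broadband burst and a rapid (~5 ms) amplitude rise; liquid onsets get a
#' gradual (>= 50 ms) formant glide from the liquid locus (F3 high for /l/,
#' low for /r/) with a slow rise; clusters get the burst followed by the
#' glide.  Words of the /eh/ set carry a final /d/-like closure and release
#' burst.  Durations are drawn near 558 ms (clamped to \[0.45, 0.67\] s) and
#' f0 near 101.9 Hz (within one semitone); the two token indices of a word
#' use different derived seeds, giving distinct realizations.  Output is
#' RMS-normalized to 0.1 and deterministic given (word, token, seed).
#'
#' @param word One row of a corpus `words` data frame (or a word label plus
#'   `corpus`).
#' @param token_index 1 or 2.
#' @param seed Integer master seed.
#' @param corpus Corpus used to resolve `word` when it is a label.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return Numeric waveform.
#' @export
make_token <- function(word, token_index = 1L, seed = 1L,
                       corpus = build_default_corpus(),
                       sample_rate = 44100) {
  if (is.character(word)) word <- word_row(corpus, word)
  stopifnot(token_index %in% c(1L, 2L))
  widx <- match(word$label, corpus$words$label)
  tseed <- carrier_seed(seed, widx,
                        if (token_index == 1L) "left" else "right", 0L)
  withr_seed(tseed, {
    duration <- min(max(stats::rnorm(1, 0.558, 0.030), 0.45), 0.67)
    f0 <- 101.9 * 2^(stats::rnorm(1, 0, 0.3) / 12)
    f0 <- min(max(f0, 101.9 * 2^(-1 / 12)), 101.9 * 2^(1 / 12))
    n <- round(duration * sample_rate)
    t <- seq_len(n) / sample_rate

    has_burst <- word$onset_class %in% c("stop", "cluster")
    has_glide <- word$onset_class %in% c("liquid", "cluster")
    t_sil <- if (has_burst) stats::runif(1, 0.005, 0.015) else 0
    t_burst <- if (has_burst) 0.008 else 0
    glide_dur <- if (has_glide) stats::runif(1, 0.05, 0.07) else 0
    v_on <- t_sil + t_burst            # voicing onset time
    rise <- if (has_glide) 0.05 else 0.005

    vf <- vowel_formants(word$vowel)
    onset_f <- if (has_glide) liquid_locus(word$liquid, vf$start)
               else vf$start
    final_d <- word$vowel == "eh"
    t_clo <- if (final_d) 0.030 else 0     # final closure
    t_rel <- if (final_d) 0.010 else 0     # final release burst
    v_end <- duration - t_clo - t_rel

    # formant trajectories, piecewise linear in time
    frac_glide <- pmin(pmax((t - v_on) / max(glide_dur, 1e-6), 0), 1)
    frac_vowel <- pmin(pmax((t - v_on - glide_dur) /
                              max(v_end - v_on - glide_dur, 1e-6), 0), 1)
    formants <- sapply(1:3, function(i) {
      via <- if (has_glide) onset_f[i] else vf$start[i]
      tr <- via + (vf$start[i] - via) * frac_glide
      tr + (vf$end[i] - vf$start[i]) * frac_vowel
    })

    # harmonic source with random phases, formant-weighted per harmonic
    bw <- c(90, 120, 180)
    peak_amp <- c(1, 0.5, 0.25)
    n_harm <- max(3L, floor(4000 / f0))
    voiced <- numeric(n)
    for (k in seq_len(n_harm)) {
      fk <- k * f0
      gain <- (1 / k) * (
        peak_amp[1] / (1 + ((fk - formants[, 1]) / bw[1])^2) +
        peak_amp[2] / (1 + ((fk - formants[, 2]) / bw[2])^2) +
        peak_amp[3] / (1 + ((fk - formants[, 3]) / bw[3])^2))
      voiced <- voiced + gain * sin(2 * pi * fk * t + stats::runif(1, 0, 2 * pi))
    }

    # flatten the source's intrinsic level drift (formant motion changes the
    # summed harmonic gain) so the amplitude contour below is authoritative
    venv <- hilbert_envelope(voiced)
    venv <- spectral_filter(venv, sample_rate, function(freqs)
      band_transfer(freqs, 0, 30, 12))
    venv <- pmax(venv, 0.05 * max(venv))
    voiced <- voiced / venv

    # amplitude contour: silence, rise, sustain, release (+ final closure)
    amp <- pmin(pmax((t - v_on) / rise, 0), 1)
    amp <- amp * pmin(pmax((v_end - t) / 0.040, 0), 1)
    x <- voiced * amp

    if (has_burst) {
      bi <- which(t >= t_sil & t < t_sil + t_burst)
      burst <- stats::rnorm(length(bi))
      burst <- burst * exp(-seq_along(bi) / (0.004 * sample_rate))
      x[bi] <- x[bi] + 1.2 * max(abs(voiced)) * burst / max(abs(burst))
    }
    if (final_d) {
      ri <- which(t >= duration - t_rel)
      if (length(ri) > 1) {
        rel <- stats::rnorm(length(ri))
        rel <- rel * exp(-seq_along(ri) / (0.003 * sample_rate))
        x[ri] <- x[ri] + 0.6 * max(abs(voiced)) * rel / max(abs(rel))
      }
    }
    x <- x + 1e-5 * stats::rnorm(n)  # low-level noise floor
    0.1 * x / rms(x)
  })
}

#' Synthesize the full corpus audio
#'
#' Generates the 15 x 2 token waveforms (deterministically from `seed`) and,
#' optionally, writes them as WAV files with the naming scheme
#' `<label>_t<token>.wav` plus a `manifest.csv` recording the realized
#' duration and f0 of every token.
#'
#' @param corpus A [build_default_corpus()] result.
#' @param seed Integer master seed.
#' @param dir Output directory for WAV files, or `NULL` to keep waveforms in
#'   memory only.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return List with `audio` (named list: `label` -> list of token
#'   waveforms), `manifest` (data frame), and `sample_rate`.
#' @export
make_corpus_audio <- function(corpus = build_default_corpus(), seed = 1L,
                              dir = NULL, sample_rate = 44100) {
  labels <- corpus$words$label
  audio <- vector("list", length(labels))
  names(audio) <- labels
  rows <- list()
  for (lab in labels) {
    toks <- lapply(seq_len(corpus$tokens_per_word), function(k)
      make_token(lab, k, seed, corpus, sample_rate))
    audio[[lab]] <- toks
    for (k in seq_along(toks)) {
      fname <- sprintf("%s_t%d.wav", lab, k)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_wav(toks[[k]] / max(abs(toks[[k]])) * 0.5,
                  file.path(dir, fname), sample_rate)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        word = lab, token = k, file = fname,
        duration_s = length(toks[[k]]) / sample_rate,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(audio = audio, manifest = manifest, sample_rate = sample_rate)
}

#' Nearest-template vowel-set classifier
#'
#' Nearest-neighbor classification of a token's vowel set from its 16-band
#' envelope-energy profile, using the mean profile of each set's tokens as
#' the template.  A sanity check that the synthetic corpus carries enough
#' spectral contrast to support vowel-based scoring.
#'
#' @param corpus_audio A [make_corpus_audio()] result.
#' @param corpus The corpus the audio was built from.
#' @param spec A [filterbank_spec()].
#' @return Data frame with columns `word`, `token`, `true_set`,
#'   `predicted_set`.
#' @export
classify_vowel_sets <- function(corpus_audio,
                                corpus = build_default_corpus(),
                                spec = filterbank_spec()) {
  w <- corpus$words
  profs <- list()
  for (lab in names(corpus_audio$audio))
    for (k in seq_along(corpus_audio$audio[[lab]]))
      profs[[paste(lab, k)]] <- list(
        word = lab, token = k, set = w$set_id[match(lab, w$label)],
        profile = band_energy_profile(corpus_audio$audio[[lab]][[k]], spec))
  sets <- unique(w$set_id)
  templates <- lapply(sets, function(s) {
    m <- sapply(profs[vapply(profs, function(p) p$set == s, TRUE)],
                function(p) p$profile / sqrt(sum(p$profile^2)))
    rowMeans(m)
  })
  names(templates) <- sets
  do.call(rbind, lapply(profs, function(p) {
    d <- vapply(templates, cosine_distance, numeric(1), a = p$profile)
    data.frame(word = p$word, token = p$token, true_set = p$set,
               predicted_set = names(which.min(d)),
               stringsAsFactors = FALSE)
  }))
}
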