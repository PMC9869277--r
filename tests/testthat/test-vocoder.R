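test_that("pink noise falls 3 dB per octave and is seeded", {
  sr <- 44100
  centers <- c(125, 250, 500, 1000, 2000, 4000)
  # average periodograms over seeds to beat estimator variance
  psum <- 0
  for (s in 1:8) {
    p <- pink_noise(2, sr, seed = s)
    psum <- psum + Mod(stats::fft(p))^2
  }
  n <- length(pink_noise(2, sr, seed = 1))
  f <- (seq_len(n) - 1) / n * sr
  oct <- vapply(centers, function(fc)
    mean(psum[f >= fc / sqrt(2) & f < fc * sqrt(2)]), numeric(1))
  steps <- diff(10 * log10(oct))
  expect_true(all(abs(steps + 3.01) < 0.5))
  expect_identical(pink_noise(0.5, seed = 3), pink_noise(0.5, seed = 3))
  expect_gt(rms(pink_noise(0.1, seed = 2)), 0)
})

test_that("A-weighting matches the standard magnitude response", {
  expect_equal(gain_db(a_weight(tone(1000)), tone(1000)), 0,
               tolerance = 0.2)
  expect_equal(gain_db(a_weight(tone(100)), tone(100)), -19.1,
               tolerance = 1)
  expect_equal(gain_db(a_weight(tone(8000)), tone(8000)), -1.1,
               tolerance = 1)
})

test_that("normalization hits the pink-noise reference level", {
  ref <- level_reference()
  refnoise <- reference_noise(ref, 0.5, seed = 6)
  renorm <- normalize_to_reference(refnoise, ref)
  expect_equal(max(abs(renorm - refnoise)) / max(abs(refnoise)), 0,
               tolerance = 1e-3)
  x <- am_tone(1500, 5, 0.5)
  y1 <- normalize_to_reference(x, ref)
  y2 <- normalize_to_reference(2 * x, ref)
  expect_equal(y1, y2, tolerance = 1e-12)
  expect_equal(dichovoc:::a_weighted_level(y1, ref), 65, tolerance = 0.1)
  expect_error(normalize_to_reference(numeric(100), ref))
})

test_that("vocoding compresses per-band envelope range by the DR percentage", {
  spec <- filterbank_spec()
  edges <- compute_band_edges(spec)
  # sustained AM tone centered in band 12
  fc <- sqrt(edges[12] * edges[13])
  x <- am_tone(fc, 6, 0.95, duration = 0.558)
  v100 <- vocode(x, 100, spec, seed = 2, details = TRUE)
  d100 <- v100$per_band[12, ]
  expect_equal(d100$range_out_db / d100$range_in_db, 1, tolerance = 0.1)
  v40 <- vocode(x, 40, spec, seed = 2, details = TRUE)
  d40 <- v40$per_band[12, ]
  expect_equal(d40$range_out_db / d40$range_in_db, 0.4, tolerance = 1e-6)
  # independent measurement on the synthesized output: the 6-Hz component
  # of the band's log-envelope (robust to carrier envelope ripple and
  # neighbor-band beating) scales with DR
  measure <- function(w) {
    band <- apply_hann_band(w, edges[12], edges[13])
    env <- extract_envelope(band)$samples
    mid <- env[round(0.15 * 44100):round(0.45 * 44100)]
    ldb <- 20 * log10(pmax(mid, 1e-8))
    X <- Mod(stats::fft(ldb - mean(ldb)))
    2 * X[round(6 * length(ldb) / 44100) + 1] / length(ldb)
  }
  r_in <- measure(x)
  r40 <- measure(v40$waveform)
  r100 <- measure(v100$waveform)
  expect_equal(r40 / r_in, 0.4, tolerance = 0.15)
  expect_equal(r100 / r_in, 1, tolerance = 0.1)
})

test_that("vocoding is deterministic and duration preserving", {
  x <- am_tone(1000, 8, 0.6, duration = 0.3)
  v1 <- vocode(x, 60, seed = 11)
  v2 <- vocode(x, 60, seed = 11)
  expect_identical(v1$waveform, v2$waveform)
  expect_length(v1$waveform, length(x))
  v3 <- vocode(x, 60, seed = 12)
  expect_false(identical(v1$waveform, v3$waveform))
  expect_error(vocode(numeric(0), 60))
})

test_that("vocoded power stays below 9 kHz with bounded low-frequency spread", {
  # half-wave rectification keeps F0-rate envelope ripple (600 Hz cutoff),
  # so low bands produce difference tones below the 250 Hz analysis edge;
  # containment is asymmetric: essentially no power above 9 kHz, a bounded
  # intermodulation floor below 125 Hz
  x <- make_token("go", 1, seed = 3)
  v <- vocode(x, 60, seed = 4)
  p <- Mod(stats::fft(v$waveform))^2
  f <- dichovoc:::fft_freqs(length(p), 44100)
  expect_gt(sum(p[f <= 9000]) / sum(p), 0.999)
  expect_gt(sum(p[f >= 125 & f <= 9000]) / sum(p), 0.8)
})

test_that("binaural stimuli use independent carriers and matched levels", {
  spec <- filterbank_spec()
  edges <- compute_band_edges(spec)
  xl <- make_token("bed", 1, seed = 5)
  xr <- make_token("led", 1, seed = 5)
  st <- binaural_vocode(xl, xr, 100, 40, spec, trial_seed = 21,
                        trial_id = 7)
  expect_equal(nrow(st), max(length(xl), length(xr)))
  ref <- level_reference()
  expect_equal(dichovoc:::a_weighted_level(st[, "left"], ref), 65,
               tolerance = 0.1)
  expect_equal(dichovoc:::a_weighted_level(st[, "right"], ref), 65,
               tolerance = 0.1)
  # wide high-frequency band: carriers from the two ears decorrelated
  bl <- apply_hann_band(st[, "left"], edges[15], edges[16])
  br <- apply_hann_band(st[, "right"], edges[15], edges[16])
  expect_lt(abs(interaural_correlation(bl, br)), 0.2)
  # unprocessed ears bypass the vocoder but are level-normalized
  un <- binaural_vocode(xl, xr, NA, NA, spec, trial_seed = 1)
  expect_equal(stats::cor(un[seq_along(xl), "left"], xl), 1,
               tolerance = 1e-6)
  # mismatched durations pad with trailing silence
  st2 <- binaural_vocode(xl[1:10000], xr, 100, 100, spec, trial_seed = 2)
  expect_equal(nrow(st2), length(xr))
})

test_that("different-vowel words stay more separable than same-vowel words", {
  corp <- build_default_corpus()
  words <- c("bed", "led", "pay", "lay", "go", "low")
  spec <- filterbank_spec()
  for (dr in c(100, 40)) {
    profs <- lapply(words, function(wl)
      band_energy_profile(vocode(make_token(wl, 1, seed = 8), dr, spec,
                                 seed = 31)$waveform, spec))
    names(profs) <- words
    vows <- corp$words$vowel[match(words, corp$words$label)]
    dists <- c(); same <- c()
    for (i in 1:(length(words) - 1)) for (j in (i + 1):length(words)) {
      d <- cosine_distance(profs[[i]], profs[[j]])
      if (vows[i] == vows[j]) same <- c(same, d) else dists <- c(dists, d)
    }
    # vowel contrast survives vocoding in aggregate: cross-vowel profile
    # distances exceed every within-vowel distance on average
    expect_gt(mean(dists), max(same))
  }
})
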