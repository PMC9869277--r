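# Shared fixtures built in code.

test_sr <- 44100

tone <- function(f, duration = 0.5, sr = test_sr, amp = 1) {
  amp * sin(2 * pi * f * seq_len(round(duration * sr)) / sr)
}

am_tone <- function(fc, fm, depth, duration = 0.5, sr = test_sr) {
  t <- seq_len(round(duration * sr)) / sr
  (1 + depth * sin(2 * pi * fm * t)) * sin(2 * pi * fc * t)
}

# Modulation depth at frequency fm from the DC and fm spectral lines of a
# non-negative envelope; robust to carrier leakage at high frequencies.
spectral_depth <- function(env, fm, sr = test_sr) {
  n <- length(env)
  X <- Mod(stats::fft(env))
  k <- round(fm * n / sr) + 1L
  2 * X[k] / X[1]
}

# dB level of one tone after filtering relative to before.
gain_db <- function(filtered, original) {
  20 * log10(dichovoc::rms(filtered) / dichovoc::rms(original))
}

make_response_df <- function(trial_id, word1, word2 = NA_character_) {
  data.frame(trial_id = trial_id, word1 = word1, word2 = word2,
             stringsAsFactors = FALSE)
}

# Respond to every trial of a schedule with a fixed rule(trial_row) -> words.
respond_all <- function(schedule, rule) {
  tr <- schedule$trials
  w1 <- character(nrow(tr)); w2 <- rep(NA_character_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    w <- rule(tr[i, ])
    w1[i] <- w[1]
    if (length(w) > 1) w2[i] <- w[2]
  }
  make_response_df(tr$trial_id, w1, w2)
}
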