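---
title: "Methods: the dichotic noise vocoder, experiment design and synthetic listener"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dichotic noise vocoder, experiment design and synthetic listener}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichovoc)
```

`dichovoc` simulates bilateral cochlear-implant listening by degrading the
temporal envelope of speech independently in the two ears and providing the
complete experimental and analytic machinery around that manipulation. This
vignette documents the processing model, the parameters that matter, the
numerical choices, and what the synthetic components do and do not emulate.

## 1. The vocoder

### Filterbank

Signals are split into `n_bands = 16` bands between `f_low = 250` and
`f_high = 8000` Hz. Band edges are equally spaced in cochlear position under
the human Greenwood map `f = 165.4 (10^(2.1 x) - 0.88)` (`x` a fraction of
basilar-membrane length), so each band occupies the same cochlear extent.
Filtering is done by multiplying the whole-signal spectrum by a real,
non-negative, zero-phase transfer function: unity inside the band, skirts
falling at `rolloff = 12` dB per octave outside. Because stimuli are short
words (~0.6 s), whole-signal spectral multiplication is both exact (no
block-boundary artifacts) and cheap.

The skirt is realized with a *constant* dB-per-octave slope in
log-frequency. A raised-cosine taper calibrated so that the slope through
its −6 dB point is 12 dB/octave reaches only ~4.5 dB attenuation one octave
past the edge and then collapses to zero; one calibrated to reach 12 dB at
one octave has an 18 dB/octave slope at −6 dB. The two properties usually
quoted for such filters — "12 dB/octave roll-off" and "~12 dB down one
octave out" — are mutually consistent only for the constant-slope form,
which is therefore what we implement. Consequences worth knowing:

* attenuation one octave outside an edge is exactly 12 dB, and repeated
  application adds attenuations in dB (tested);
* skirts never reach zero, so neighboring bands overlap and measurements of
  a single band on a mixed signal pick up neighbor leakage;
* the carriers are effectively much more sharply band-limited than a single
  filter pass, because the low-noise-noise refinement re-applies the band
  filter at every iteration (11 passes in total).

### Envelope extraction

Band envelopes are extracted by half-wave rectification followed by the same
spectral machinery as a low-pass from 0 to `env_cutoff = 600` Hz; residual
ringing below zero is clipped so envelopes are non-negative. A 600-Hz cutoff
deliberately retains voice-pitch periodicity (F0 ≈ 102 Hz and several
harmonics) in the envelope. Two knock-on effects are intrinsic to this
recipe, not implementation artifacts:

* for bands lying near or below the cutoff, the "envelope" retains temporal
  fine structure;
* when an envelope carrying F0-rate ripple multiplies a low-frequency
  carrier (250–550 Hz bands), difference tones land below the 250 Hz
  analysis edge. In the full vocoded output roughly 10 % of power falls
  below 125 Hz for the synthetic talker; essentially none falls above
  9 kHz. The spectral-containment test asserts exactly this asymmetric
  behavior.

### Dynamic-range compression

The core manipulation compresses each band envelope to `dr_percent` of its
original dB range. The samplewise rule, applied with the envelope pinned so
its maximum sits at `max_db = 90` dB, is

    E_compressed = E_full + (100 - DR)/100 * (Max - E_full)

i.e. dips are filled in toward the maximum. The eleven-step procedure around
it: add a small offset `epsilon`; convert to dB; shift the maximum to 90 dB;
apply the rule; shift back; convert to linear; remove the offset; zero
sub-threshold samples; low-pass again at 600 Hz; rescale to the original
envelope RMS. Exact invariants (tested to 1e-9 relative, over random
envelopes):

* after the rule and before re-filtering, the envelope's dB range is
  exactly `DR` percent of its input range, and sample ordering is preserved
  for `DR > 0`;
* the rule composes multiplicatively: DR₁ then DR₂ equals DR₁·DR₂/100;
* the final RMS equals the input RMS (within 0.1 dB; the rescale is the
  last step).

Numerical choices: `epsilon = 1e-6 ×` the envelope maximum and the step-9
floor equals `epsilon`, so the offset insertion/removal and flooring are
inverses up to negligible residue; neither constant is critical and both are
overridable in `compression_spec()`. An all-zero envelope is returned
unchanged (it has no range to compress; dividing by its RMS would be
undefined). `compress_extremes()` is the idealized midpoint-preserving
description of what compression does to the extremes (40–70 dB at 60 % →
46–64 dB, range 18 dB); the full procedure's realized extremes also depend
on the envelope's amplitude distribution through the RMS rescale.

## 2. Carriers and level calibration

Carriers are **low-noise noise**: band-limited Gaussian noise refined by
`n_iterations = 10` rounds of dividing by its own Hilbert envelope (floored
at 1e-6 of maximum) and re-band-limiting. Envelope fluctuation
(`sd/mean` of the Hilbert envelope) drops several-fold and is
non-increasing across iterations (tested), so the imposed speech envelope
dominates the modulation a listener receives.

Every carrier's seed is derived deterministically from
`(schedule seed, trial, ear, band)` by an integer hash (`carrier_seed()`),
so a full experiment regenerates bit-identically while the two ears and all
bands use independent noise. The zero-lag interaural correlation of two
independent band-limited noises of duration `T` and bandwidth `B` has
standard deviation ≈ `1/sqrt(2BT)` — for 558-ms stimuli this is ~0.10 in the
narrowest Greenwood band (≈82 Hz wide) and ~0.02 in the widest. Single-trial
correlations in narrow bands therefore scatter to ±0.2 even though carriers
are exactly independent by construction; tests assert the
bandwidth-dependent bound, and expectations of |r| below it.

Levels: stimuli are RMS-normalized so their A-weighted level (IEC 61672
magnitude response, zero phase) equals that of pink noise (1/f PSD from
20 Hz up) rendered at `target_db_a = 65` dB(A). Digital full scale is
calibrated to 100 dB SPL by default; absolute SPL is a playback property, so
only relative levels are contractual. Normalization is applied per ear —
each channel is equated to the reference independently — matching the
stimulus description's per-signal RMS normalization. The unprocessed
condition bypasses vocoding but is still level-normalized.

## 3. The experiment design

The corpus is 3 rhyme sets × 5 monosyllables (bed/led/red/bled/bred,
pay/lay/ray/play/pray, go/low/row/glow/grow): per set one stop-onset word,
two liquids (/l/, /r/) and both stop–liquid clusters, all sharing the set's
vowel. Trial families and per-condition counts:

| family | construction | n |
|---|---|---|
| same_word | each word × 10 repeats, different tokens per ear | 150 |
| different_vowel | all ordered cross-set pairs, once each | 150 |
| fusion | stop-only × each liquid-only, 2/set × 3 sets × 2 ear orders × 5 repeats | 60 |
| other_rhyme | the 8 (= C(5,2) − 2) non-fusible same-set pairs × 2 ear orders × 2 repeats | 96 |

With 7 vocoder conditions (unprocessed; 100, 60, 40 % symmetric; 100:60,
100:40, 60:40 asymmetric) the schedule holds 456 × 7 = 3,192 trials. Blocks
draw equal quotas from every condition × family cell; cells not divisible by
10 put their remainder in the final block, which reproduces nine blocks of
315 and a final block of 357. Design choices that were genuinely open:

* the non-fusible same-set pairings are counted as all 8 combinations per
  set (C(5,2) minus the 2 fusible pairs), which is the only count consistent
  with the 96-trial total;
* different-vowel pairings are the 150 *ordered* pairs presented once each
  (rather than 75 unordered × 2 ear orders — the trial count is the same);
* in asymmetric conditions the ear receiving the smaller dynamic range is a
  schedule-level flag (`asym_small_dr_ear`), the design's counterbalancing
  unit;
* one integer seed drives a single generator for ordering and token
  choice; same-word trials always use the two distinct tokens.

Responses contain one or two words from the corpus, so there are
15 + C(15,2) = 120 legal response combinations and chance is 1/120.

## 4. Scoring

Same-word trials are correct only for a one-word exact match (two-word
responses are incorrect by definition, so accuracy is bounded above by the
one-word proportion). Different-vowel accuracy is "at least one presented
word reported"; for one-word responses the reported word's *vowel*
attributes the response to an ear (vowel errors are rare under this
manipulation, so the vowel tracks the attended ear), with
vowel-matches-neither tallied as `neither` and excluded from ear-proportion
denominators.

Fusion trials use a five-way taxonomy with a fixed priority:
**ideal** (both words reported) > **fused** (one word, the cluster
combining the presented stop and liquid) > **biased_left/right** (only the
named ear's word correct, whether one or two words were reported) >
**interference** (nothing corresponding to either ear or the cluster). The
priority resolves response patterns the category definitions alone do not
order: a two-word response containing the cluster plus one presented word
counts as biased toward that ear; the cluster plus an unrelated word is
interference. Other-rhyme trials use the same taxonomy minus `fused` (they
have no legal cluster target). A property test checks the classifier against
an independently coded brute-force rule table on all 120 responses × 12
fusible presentations, confirming the categories partition the response
space.

Aggregation is descriptive: per condition × family cell, accuracies and
response-type proportions with seeded percentile-bootstrap CIs over trials.
Inferential mixed-effects modelling is deliberately out of scope.

## 5. Synthetic speech

`make_token()` is a source–filter synthesizer: a harmonic source near
101.9 Hz (within one semitone; durations drawn near 558 ms, clamped to
0.45–0.67 s) shaped by three formant resonances. Vowel targets are textbook
male values — /ε/ (550, 1800, 2500 Hz), /eɪ/ (550→400, 1900→2200,
2600→2800 Hz), /oʊ/ (500→450, 1000→850, 2400→2300 Hz) — with liquids
distinguished by the F3 locus (high for /l/, strongly lowered for /r/).
Onsets realize the corpus structure: stops get 5–15 ms silence, an 8-ms
broadband burst and a 5-ms rise; liquids a ≥50 ms formant glide and 50-ms
rise; clusters burst-then-glide. The /ε/ set carries a final /d/-like
closure and release. The source's intrinsic level drift (formant motion
changes summed harmonic gain) is flattened by its own smoothed Hilbert
envelope so the amplitude contour is authoritative — this is what makes
rise-time contrasts (stop < liquid) hold by construction.

What the generator emulates: the corpus's onset-class and vowel structure,
token-to-token microvariation, duration/F0 statistics, and enough spectral
contrast that a nearest-template classifier on 16-band envelope profiles
identifies every clean token's vowel set. What it does not emulate: talker
realism, coarticulation, natural prosody, or the specific acoustics of the
original recordings — so passing tests demonstrate that the *pipeline*
preserves and scores these contrasts, not that results would transfer
quantitatively to real speech. One measured caveat: after vocoding, profile
distances between the /eɪ/ and /oʊ/ sets shrink to the same-vowel range for
the weakest pairs (band-skirt leakage plus flat-spectrum carriers), so the
vowel-separability check on vocoded audio is asserted in aggregate (mean
cross-vowel distance exceeds every same-vowel distance) rather than
pairwise.

## 6. The synthetic listener

`simulate_response()` is deliberately simple — a test harness, not a
cognitive model. All functional forms in one place:

* per-ear identification: `p(DR) = plogis(qlogis(0.75) +
  intelligibility_slope · (DR − intelligibility_midpoint))`; unprocessed is
  treated as DR = 100;
* misheard words are corrupted within the rhyme set, with
  liquid↔cluster substitutions favored (probability 0.5 to the
  liquid-sharing neighbor, else uniform over the set) — echoing the
  dominant confusion this manipulation produces;
* one-word (fused) response probability: `fusion_base + fusion_dr_gain ×
  (100 − mean DR)`, clamped to [0, 1]; if not fusing, identical heard words
  still yield one word;
* the attended ear for one-word responses is right with probability
  `right_ear_weight + better_ear_gain × (DR_right − DR_left)`, clamped;
* with probability `lapse`, the response is uniform over the 120 legal
  combinations.

Defaults (midpoint 45 %, slope 0.08/%, fusion_base 0.3, fusion_dr_gain
0.006/%, right_ear_weight 0.55, better_ear_gain 0.004/%, lapse 0.02) were
chosen once as a plausible younger-normal-hearing-like profile: ceiling-level
identification unprocessed, substantial degradation at 40 % DR, a modest
right-ear bias, and more one-word responses as DR falls. The `onh` preset
differs qualitatively (more fusion growth with degradation, more lapses,
stronger right-ear weighting) without asserting any measured human values.

`fit_listener_params()` recovers `right_ear_weight`, `fusion_base`,
`fusion_dr_gain` and `intelligibility_midpoint` by maximum likelihood from
per-condition sufficient statistics: same-word correctness (Bernoulli),
the different-vowel response type (two-word / one-word left / right /
neither; multinomial — the corruption channel preserves vowels, which makes
these probabilities exact), and one-word counts in the same-word and
rhyming families, whose collision probabilities (both ears hearing the same
word without fusing) are computed exactly from the corruption channel as a
bilinear form in the per-ear accuracies and averaged over each family's
pairings. A coarse grid seeds a Nelder–Mead refinement; `lapse`,
`intelligibility_slope` and `better_ear_gain` are held fixed. Recovery is
validated by simulation: across 20 replicates of the full 3,192-trial
schedule, `right_ear_weight` and `fusion_base` return within ±0.05 of
truth.

## 7. Problem sizes and numerical notes

* Spectral operations zero-pad to the next 7-smooth length (R's FFT is
  quadratic for lengths with large prime factors) and trim; envelope
  low-pass residuals below zero are clipped.
* Property tests use 0.3–0.6 s signals at 44.1 kHz, 25–100 random envelopes
  per invariant, 40–100 carrier pairs per band for correlation statistics,
  and 20 simulation replicates for parameter recovery; all seeds are fixed
  in the tests themselves.
* WAV I/O (PCM 16/24-bit and float32, mono/stereo) is implemented in base R
  (`read_wav()`/`write_wav()`); integer formats clip rather than wrap.
* Degenerate inputs: empty signals error; all-zero envelopes pass through
  compression unchanged; zero-energy signals cannot be level-normalized or
  correlated (error); duration-mismatched binaural inputs are padded with
  trailing silence.

## 8. Known limitations

* The vocoder's low-frequency intermodulation floor (section 1) means the
  output is not strictly band-limited to the analysis range; a playback
  high-pass would remove it but is not part of the described processing.
* Narrow-band interaural correlation cannot be verified below the
  `1/sqrt(2BT)` statistical floor on single trials (section 2);
  independence is guaranteed by construction (disjoint seeds) and verified
  in expectation.
* The listener model's corruption channel is fixed, not fitted; it is a
  nuisance mechanism chosen to generate realistic confusion structure, and
  only the four parameters named above are estimated.
* Scoring follows a literal reading of the category definitions; the
  priority resolution of responses containing the cluster word plus a
  presented word is a documented choice, not an empirical fact.
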