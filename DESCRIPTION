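Package: dichovoc
Title: Dichotic Noise-Vocoder Simulation of Bilateral Cochlear Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating bilateral cochlear-implant listening with a
    noise vocoder whose band envelopes are compressed in the dB domain to a
    chosen percentage of their original dynamic range. Provides a
    Greenwood-spaced spectral filterbank with temporal-envelope extraction,
    dB-domain envelope compression, low-noise-noise carriers with controlled
    interaural independence, binaural stimulus assembly with pink-noise
    A-weighted level normalization, the complete counterbalanced dichotic
    word-pair experiment design (same-word, different-vowel, phonological
    fusion and other-rhyme trial families), deterministic response scoring
    (accuracy, fusion taxonomy, ear advantage, vowel confusions,
    liquid-substitution analysis), a synthetic pseudo-speech corpus generator,
    and a generative synthetic-listener model with maximum-likelihood
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
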