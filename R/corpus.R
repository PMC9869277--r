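#' The 15-word dichotic rhyme corpus
#'
#' Builds the three rhyme sets of five monosyllables each used in the
#' dichotic word experiment.  Each set shares a vowel and contains one
#' stop-onset word, two liquid-onset words (/l/ and /r/), and the two
#' stop-liquid cluster words obtained by combining the stop with each liquid:
#' \{bed, led, red, bled, bred\}, \{pay, lay, ray, play, pray\} and
#' \{go, low, row, glow, grow\}.
#'
#' @param tokens_per_word Number of recorded/synthesized tokens per word
#'   (default 2).
#' @return An object of class `corpus`: list with `words` (data frame with
#'   columns `label`, `set_id`, `onset_class`, `stop`, `liquid`, `vowel`) and
#'   `tokens_per_word`.
#' @examples
#' corp <- build_default_corpus()
#' table(corp$words$set_id, corp$words$onset_class)
#' @export
build_default_corpus <- function(tokens_per_word = 2L) {
  sets <- list(
    ED = list(vowel = "eh", stop = "b",
              words = c(stop = "bed", l = "led", r = "red",
                        cl = "bled", cr = "bred")),
    AY = list(vowel = "ei", stop = "p",
              words = c(stop = "pay", l = "lay", r = "ray",
                        cl = "play", cr = "pray")),
    OW = list(vowel = "ou", stop = "g",
              words = c(stop = "go", l = "low", r = "row",
                        cl = "glow", cr = "grow")))
  rows <- lapply(names(sets), function(sid) {
    s <- sets[[sid]]
    data.frame(
      label = unname(s$words),
      set_id = sid,
      onset_class = c("stop", "liquid", "liquid", "cluster", "cluster"),
      stop = c(s$stop, NA, NA, s$stop, s$stop),
      liquid = c(NA, "l", "r", "l", "r"),
      vowel = s$vowel,
      stringsAsFactors = FALSE)
  })
  words <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(words$label))
  structure(list(words = words, tokens_per_word = as.integer(tokens_per_word)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("Corpus: %d words in %d sets, %d tokens per word\n",
              nrow(x$words), length(unique(x$words$set_id)),
              x$tokens_per_word))
  invisible(x)
}

word_row <- function(corpus, label) {
  i <- match(label, corpus$words$label)
  if (any(is.na(i))) stop("unknown word label: ",
                          paste(label[is.na(i)], collapse = ", "))
  corpus$words[i, , drop = FALSE]
}

# The cluster word formed by a (stop-only, liquid-only) same-set pair,
# or NA if the pair is not fusible.
fusion_target <- function(corpus, label_a, label_b) {
  a <- word_row(corpus, label_a); b <- word_row(corpus, label_b)
  if (a$set_id != b$set_id) return(NA_character_)
  cls <- c(a$onset_class, b$onset_class)
  if (!setequal(cls, c("stop", "liquid"))) return(NA_character_)
  stopc <- if (a$onset_class == "stop") a$stop else b$stop
  liq <- if (a$onset_class == "liquid") a$liquid else b$liquid
  w <- corpus$words
  hit <- w$label[w$set_id == a$set_id & w$onset_class == "cluster" &
                 w$stop == stopc & w$liquid == liq]
  if (length(hit) == 1L) hit else NA_character_
}

#' Enumerate word pairings for one trial family
#'
#' Expands the complete list of left/right word pairings (repeats included)
#' for one of the four trial families:
#' \describe{
#'   \item{same_word}{each of the 15 words, 10 repeats (150 trials; the two
#'     ears get different tokens of the same word).}
#'   \item{different_vowel}{every ordered cross-set pair, once each
#'     (15 x 10 = 150 trials).}
#'   \item{fusion}{the stop-only word of a set paired with each of its two
#'     liquid-only words; 2 pairs x 3 sets x 2 ear orders x 5 repeats = 60.}
#'   \item{other_rhyme}{the 8 non-fusible same-set pairs per set
#'     (C(5,2) - 2), x 3 sets x 2 ear orders x 2 repeats = 96.}
#' }
#'
#' @param corpus A [build_default_corpus()] result.
#' @param family One of `"same_word"`, `"different_vowel"`, `"fusion"`,
#'   `"other_rhyme"`.
#' @return Data frame with columns `family`, `left_word`, `right_word`, one
#'   row per trial instance (per vocoder condition).
#' @export
enumerate_trials <- function(corpus, family) {
  stopifnot(inherits(corpus, "corpus"))
  family <- match.arg(family, c("same_word", "different_vowel", "fusion",
                                "other_rhyme"))
  w <- corpus$words
  pairs <- switch(family,
    same_word = {
      data.frame(left_word = rep(w$label, each = 10),
                 right_word = rep(w$label, each = 10))
    },
    different_vowel = {
      grid <- expand.grid(left_word = w$label, right_word = w$label,
                          stringsAsFactors = FALSE)
      vl <- w$vowel[match(grid$left_word, w$label)]
      vr <- w$vowel[match(grid$right_word, w$label)]
      grid[vl != vr, ]
    },
    fusion = {
      out <- lapply(unique(w$set_id), function(sid) {
        s <- w[w$set_id == sid, ]
        stopw <- s$label[s$onset_class == "stop"]
        liqs <- s$label[s$onset_class == "liquid"]
        pair <- expand.grid(a = stopw, b = liqs, stringsAsFactors = FALSE)
        both <- rbind(data.frame(left_word = pair$a, right_word = pair$b),
                      data.frame(left_word = pair$b, right_word = pair$a))
        both[rep(seq_len(nrow(both)), each = 5), ]
      })
      do.call(rbind, out)
    },
    other_rhyme = {
      out <- lapply(unique(w$set_id), function(sid) {
        s <- w[w$set_id == sid, ]
        cmb <- utils::combn(s$label, 2)
        keep <- apply(cmb, 2, function(p)
          is.na(fusion_target(corpus, p[1], p[2])))
        cmb <- cmb[, keep, drop = FALSE]
        both <- rbind(data.frame(left_word = cmb[1, ], right_word = cmb[2, ]),
                      data.frame(left_word = cmb[2, ], right_word = cmb[1, ]))
        both[rep(seq_len(nrow(both)), each = 2), ]
      })
      do.call(rbind, out)
    })
  rownames(pairs) <- NULL
  cbind(data.frame(family = family, stringsAsFactors = FALSE), pairs)
}

#' Chance performance of the response task
#'
#' Listeners report one or two words from the corpus, so there are
#' `n + choose(n, 2)` legal response combinations; chance accuracy is the
#' reciprocal.  For the default 15-word corpus: 15 singles + 105 pairs = 120
#' combinations, chance 1/120.
#'
#' @param corpus A `corpus` (>= 2 words).
#' @return List with `n_single`, `n_pairs`, `n_total`, `probability`.
#' @export
chance_level <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  n <- nrow(corpus$words)
  if (n < 2) stop("corpus must contain at least 2 words")
  n_pairs <- choose(n, 2)
  list(n_single = n, n_pairs = n_pairs, n_total = n + n_pairs,
       probability = 1 / (n + n_pairs))
}

#' The canonical seven vocoder conditions
#'
#' Unprocessed speech, three interaurally symmetric dynamic ranges (100, 60,
#' 40 percent) and three asymmetric ones (100:60, 100:40, 60:40).  For the
#' asymmetric conditions `dr_big`/`dr_small` are mapped onto ears by the
#' schedule's counterbalance flag.
#'
#' @return Data frame with columns `label`, `dr_big`, `dr_small` (`NA` for
#'   unprocessed).
#' @export
vocoder_conditions <- function() {
  data.frame(
    label = c("unprocessed", "100:100", "60:60", "40:40",
              "100:60", "100:40", "60:40"),
    dr_big = c(NA, 100, 60, 40, 100, 100, 60),
    dr_small = c(NA, 100, 60, 40, 60, 40, 40),
    stringsAsFactors = FALSE)
}
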