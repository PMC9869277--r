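normalize_response <- function(word1, word2) {
  words <- c(word1, word2)
  words <- words[!is.na(words) & nzchar(words)]
  if (length(words) < 1 || length(words) > 2)
    stop("a response must contain 1 or 2 words")
  if (length(words) == 2 && words[1] == words[2]) words <- words[1]
  words
}

#' Score one same-word trial
#'
#' A response is correct only when it contains exactly one word and that
#' word is the presented label; any two-word response is incorrect.
#'
#' @param trial One row of a schedule's `trials` data frame
#'   (`family == "same_word"`).
#' @param words Character vector of 1 or 2 reported word labels.
#' @param corpus The corpus.
#' @return List with `n_words`, `correct_same_word`, `liquid_only`.
#' @export
score_same_word <- function(trial, words, corpus = build_default_corpus()) {
  if (trial$family != "same_word") stop("trial is not a same_word trial")
  words <- normalize_response(words[1], words[2][length(words) >= 2])
  list(n_words = length(words),
       correct_same_word = length(words) == 1 && words == trial$left_word,
       liquid_only = all_liquid_only(words, corpus))
}

all_liquid_only <- function(words, corpus) {
  cls <- corpus$words$onset_class[match(words, corpus$words$label)]
  all(cls == "liquid")
}

#' Score one different-vowel trial
#'
#' Accuracy is the probability of reporting at least one presented word.
#' For one-word responses, the vowel of the reported word attributes the
#' response to an ear: `left`/`right` if it matches exactly one presented
#' side, `neither` if it matches neither (both sides' vowels always differ
#' in this family).
#'
#' @inheritParams score_same_word
#' @return List with `n_words`, `at_least_one_correct`, `ear_attribution`
#'   (`NA` for two-word responses), `liquid_only`.
#' @export
score_different_vowel <- function(trial, words,
                                  corpus = build_default_corpus()) {
  if (trial$family != "different_vowel")
    stop("trial is not a different_vowel trial")
  words <- normalize_response(words[1], words[2][length(words) >= 2])
  presented <- c(trial$left_word, trial$right_word)
  attribution <- NA_character_
  if (length(words) == 1) {
    v <- corpus$words$vowel[match(words, corpus$words$label)]
    vl <- corpus$words$vowel[match(trial$left_word, corpus$words$label)]
    vr <- corpus$words$vowel[match(trial$right_word, corpus$words$label)]
    attribution <- if (v == vl && v == vr) "both"
      else if (v == vl) "left" else if (v == vr) "right" else "neither"
  }
  list(n_words = length(words),
       at_least_one_correct = length(intersect(words, presented)) > 0,
       ear_attribution = attribution,
       liquid_only = all_liquid_only(words, corpus))
}

#' Classify a fusion-trial response into the five-way taxonomy
#'
#' Priority classification of a response to a dichotic stop/liquid pair:
#' \describe{
#'   \item{ideal}{two words, both presented words reported.}
#'   \item{fused}{one word equal to the same-set cluster combining the
#'     presented stop and liquid (e.g. bed + led -> bled).}
#'   \item{biased_left / biased_right}{one or two words with only the named
#'     ear's word correct.}
#'   \item{interference}{anything corresponding to neither presented word
#'     nor the fused cluster.}
#' }
#' Other-rhyme trials use the same taxonomy without `fused` (they have no
#' legal cluster target).
#'
#' @inheritParams score_same_word
#' @return Category string.
#' @export
classify_fusion_response <- function(trial, words,
                                     corpus = build_default_corpus()) {
  if (!trial$family %in% c("fusion", "other_rhyme"))
    stop("trial is not a fusion or other_rhyme trial")
  words <- normalize_response(words[1], words[2][length(words) >= 2])
  left <- trial$left_word; right <- trial$right_word
  has_left <- left %in% words
  has_right <- right %in% words
  if (has_left && has_right) return("ideal")
  if (trial$family == "fusion") {
    target <- fusion_target(corpus, left, right)
    if (length(words) == 1 && !is.na(target) && words == target)
      return("fused")
  }
  if (has_left) return("biased_left")
  if (has_right) return("biased_right")
  "interference"
}

#' Score a full response table against a schedule
#'
#' Joins responses to the schedule by `trial_id` and applies the
#' family-appropriate scoring: same-word exact accuracy, different-vowel
#' at-least-one accuracy with vowel-based ear attribution, and the fusion
#' taxonomy for fusion and other-rhyme trials.
#'
#' @param schedule A [build_schedule()] result.
#' @param responses Data frame with columns `trial_id`, `word1`, `word2`
#'   (`word2` may be `NA` for one-word responses).
#' @param corpus The corpus.
#' @return Data frame of scored trials: schedule columns plus `word1`,
#'   `word2`, `n_words`, `correct_same_word`, `at_least_one_correct`,
#'   `category`, `ear_attribution`, `liquid_only`.
#' @export
score_trials <- function(schedule, responses,
                         corpus = build_default_corpus()) {
  stopifnot(inherits(schedule, "schedule"))
  tr <- schedule$trials
  idx <- match(tr$trial_id, responses$trial_id)
  if (anyNA(idx)) stop("responses missing for ",
                       sum(is.na(idx)), " trial(s)")
  out <- tr
  out$word1 <- responses$word1[idx]
  out$word2 <- responses$word2[idx]
  n <- nrow(out)
  out$n_words <- integer(n)
  out$correct_same_word <- NA
  out$at_least_one_correct <- NA
  out$category <- NA_character_
  out$ear_attribution <- NA_character_
  out$liquid_only <- NA
  for (i in seq_len(n)) {
    trial <- out[i, ]
    words <- normalize_response(trial$word1, trial$word2)
    out$n_words[i] <- length(words)
    presented <- c(trial$left_word, trial$right_word)
    out$at_least_one_correct[i] <- length(intersect(words, presented)) > 0
    out$liquid_only[i] <- all_liquid_only(words, corpus)
    if (trial$family == "same_word") {
      out$correct_same_word[i] <-
        length(words) == 1 && words == trial$left_word
    } else if (trial$family == "different_vowel") {
      s <- score_different_vowel(trial, words, corpus)
      out$ear_attribution[i] <- s$ear_attribution
    } else {
      out$category[i] <- classify_fusion_response(trial, words, corpus)
    }
  }
  out
}

boot_ci <- function(x, n_boot, level) {
  if (length(x) == 0 || n_boot < 1) return(c(NA_real_, NA_real_))
  means <- vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE))
}

#' Aggregate scored trials per condition and family
#'
#' Descriptive aggregation: per (vocoder condition x trial family) cell,
#' the family's accuracy, the one- and two-word response proportions, and
#' (for fusion/other-rhyme) category relative frequencies, each with a
#' seeded percentile-bootstrap confidence interval over trials.
#'
#' @param scored A [score_trials()] result.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List with `summary` (one row per cell) and `categories` (one row
#'   per cell x category with `prop`, `lo`, `hi`).
#' @export
aggregate_scores <- function(scored, n_boot = 1000L, level = 0.95,
                             seed = 1L) {
  if (nrow(scored) == 0) stop("no scored trials")
  cells <- split(scored, list(scored$condition_label, scored$family),
                 drop = TRUE)
  withr_seed(as.integer(seed), {
    summ <- do.call(rbind, lapply(cells, function(d) {
      acc <- switch(d$family[1],
                    same_word = as.numeric(d$correct_same_word),
                    as.numeric(d$at_least_one_correct))
      ci <- boot_ci(acc, n_boot, level)
      one <- as.numeric(d$n_words == 1)
      cio <- boot_ci(one, n_boot, level)
      data.frame(condition_label = d$condition_label[1],
                 family = d$family[1], n = nrow(d),
                 accuracy = mean(acc), acc_lo = ci[1], acc_hi = ci[2],
                 p_one_word = mean(one), p_one_lo = cio[1], p_one_hi = cio[2],
                 p_two_word = 1 - mean(one),
                 stringsAsFactors = FALSE)
    }))
    cats <- do.call(rbind, lapply(cells, function(d) {
      if (all(is.na(d$category))) return(NULL)
      levs <- c("ideal", "fused", "biased_left", "biased_right",
                "interference")
      do.call(rbind, lapply(levs, function(lv) {
        x <- as.numeric(d$category == lv)
        ci <- boot_ci(x, n_boot, level)
        data.frame(condition_label = d$condition_label[1],
                   family = d$family[1], category = lv,
                   prop = mean(x), lo = ci[1], hi = ci[2],
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(summ) <- NULL
  if (!is.null(cats)) rownames(cats) <- NULL
  list(summary = summ, categories = cats)
}

#' Ear advantage / ear bias
#'
#' For different-vowel trials, the proportion of one-word responses whose
#' vowel is attributed to each ear (responses attributed to neither side are
#' excluded from the denominator).  For fusion trials, the proportion of
#' biased responses naming each ear.  With `mode = "better_worse"` the sides
#' are recoded by dynamic range (the ear with the larger DR is "better");
#' this requires asymmetric conditions and errors on symmetric ones.
#'
#' @param scored A [score_trials()] result.
#' @param mode `"left_right"` or `"better_worse"`.
#' @param family `"different_vowel"` (vowel attribution) or `"fusion"`
#'   (word-identity attribution).
#' @param conditions Optional character vector restricting the vocoder
#'   conditions analyzed.
#' @return Data frame per condition: `n` qualifying trials and the two ear
#'   proportions.
#' @export
ear_advantage <- function(scored, mode = c("left_right", "better_worse"),
                          family = c("different_vowel", "fusion"),
                          conditions = NULL) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  d <- scored[scored$family == family, , drop = FALSE]
  if (!is.null(conditions))
    d <- d[d$condition_label %in% conditions, , drop = FALSE]
  if (family == "different_vowel") {
    d <- d[d$n_words == 1 & d$ear_attribution %in% c("left", "right"), ,
           drop = FALSE]
    d$side <- d$ear_attribution
  } else {
    d <- d[d$category %in% c("biased_left", "biased_right"), , drop = FALSE]
    d$side <- sub("biased_", "", d$category)
  }
  if (mode == "better_worse") {
    sym <- is.na(d$dr_left) | d$dr_left == d$dr_right
    if (any(sym))
      stop("better/worse recoding requires asymmetric conditions")
    better_side <- ifelse(d$dr_left > d$dr_right, "left", "right")
    d$side <- ifelse(d$side == better_side, "better", "worse")
  }
  labs <- if (mode == "left_right") c("left", "right") else
    c("better", "worse")
  out <- do.call(rbind, lapply(split(d, d$condition_label), function(g) {
    p <- c(mean(g$side == labs[1]), mean(g$side == labs[2]))
    df <- data.frame(condition_label = g$condition_label[1], n = nrow(g),
                     p1 = p[1], p2 = p[2], stringsAsFactors = FALSE)
    names(df)[3:4] <- paste0("prop_", labs)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Vowel confusion matrix
#'
#' Counts of reported vowel combinations by presented vowel pairing.  Rows
#' are presented pairings (sorted vowel pairs, e.g. `"eh+ei"`, or a single
#' vowel for same-vowel trials), columns are reported combinations; row sums
#' equal the number of trials per pairing.
#'
#' @param scored A [score_trials()] result.
#' @param corpus The corpus.
#' @return Integer matrix of counts.
#' @export
vowel_confusions <- function(scored, corpus = build_default_corpus()) {
  if (nrow(scored) == 0) stop("no scored trials")
  vow <- function(lab) corpus$words$vowel[match(lab, corpus$words$label)]
  combo <- function(v) paste(sort(unique(v)), collapse = "+")
  presented <- vapply(seq_len(nrow(scored)), function(i)
    combo(vow(c(scored$left_word[i], scored$right_word[i]))), "")
  reported <- vapply(seq_len(nrow(scored)), function(i) {
    w <- c(scored$word1[i], scored$word2[i])
    combo(vow(w[!is.na(w) & nzchar(w)]))
  }, "")
  table(presented = presented, reported = reported)
}

#' Proportion of liquid-only responses
#'
#' Proportion of trials whose response consists solely of liquid-onset
#' singletons (led, red, lay, ray, low, row) — the substitution analysis for
#' stop/liquid material.  A uniform single-word guesser sits at 6/15 = 0.4.
#'
#' @param scored A [score_trials()] result.
#' @param family `"same_word"` or `"fusion"`.
#' @param conditions Optional condition filter.
#' @return Data frame per condition with `n` and `prop_liquid_only`.
#' @export
liquid_only_proportion <- function(scored,
                                   family = c("same_word", "fusion"),
                                   conditions = NULL) {
  family <- match.arg(family)
  d <- scored[scored$family == family, , drop = FALSE]
  if (!is.null(conditions))
    d <- d[d$condition_label %in% conditions, , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, d$condition_label), function(g)
    data.frame(condition_label = g$condition_label[1], n = nrow(g),
               prop_liquid_only = mean(g$liquid_only),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
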