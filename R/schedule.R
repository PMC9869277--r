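#' Build the complete counterbalanced trial schedule
#'
#' Enumerates every trial-family pairing under every vocoder condition
#' (456 pairings x 7 conditions = 3,192 trials) and lays them out in 10
#' blocks.  Each block draws an equal quota from every
#' (condition x family) cell; cells whose count is not divisible by 10 place
#' their remainder in the final block, giving nine blocks of 315 trials and a
#' final block of 357.  Trial order within a block, and token choices, are a
#' seeded permutation, so two schedules built with the same seed are
#' identical.
#'
#' Token assignment: same-word trials use the two distinct tokens (order
#' randomized); all other families draw each side's token at random.  In
#' asymmetric conditions the smaller dynamic range is assigned to
#' `asym_small_dr_ear`.
#'
#' @param corpus A [build_default_corpus()] result.
#' @param conditions Condition table from [vocoder_conditions()] (the
#'   canonical seven; anything else is an error).
#' @param seed Integer seed driving ordering and token choice.
#' @param asym_small_dr_ear `"left"` or `"right"`: which ear receives the
#'   smaller dynamic range in asymmetric conditions.
#' @param n_blocks Number of blocks (default 10).
#' @return An object of class `schedule`: list with `trials` (data frame with
#'   columns `trial_id`, `block`, `position`, `family`, `left_word`,
#'   `left_token`, `right_word`, `right_token`, `condition_label`, `dr_left`,
#'   `dr_right`), `seed`, `asym_small_dr_ear`, `n_blocks`.
#' @examples
#' sched <- build_schedule(build_default_corpus(), seed = 1)
#' table(sched$trials$block)
#' @export
build_schedule <- function(corpus, conditions = vocoder_conditions(),
                           seed = 1L, asym_small_dr_ear = c("left", "right"),
                           n_blocks = 10L) {
  stopifnot(inherits(corpus, "corpus"))
  asym_small_dr_ear <- match.arg(asym_small_dr_ear)
  canon <- vocoder_conditions()
  if (!identical(dim(conditions), dim(canon)) ||
      !setequal(conditions$label, canon$label))
    stop("conditions must be the canonical seven vocoder conditions")

  families <- c("same_word", "different_vowel", "fusion", "other_rhyme")
  fam_pairs <- lapply(families, enumerate_trials, corpus = corpus)
  names(fam_pairs) <- families

  withr_seed(as.integer(seed), {
    cells <- list()
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      if (cond$label == "unprocessed") {
        dl <- NA_real_; dr_ <- NA_real_
      } else if (asym_small_dr_ear == "left") {
        dl <- cond$dr_small; dr_ <- cond$dr_big
      } else {
        dl <- cond$dr_big; dr_ <- cond$dr_small
      }
      for (fam in families) {
        p <- fam_pairs[[fam]]
        n <- nrow(p)
        p <- p[sample.int(n), , drop = FALSE]
        if (fam == "same_word") {
          flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
          p$left_token <- ifelse(flip, 1L, 2L)
          p$right_token <- ifelse(flip, 2L, 1L)
        } else {
          p$left_token <- sample(corpus$tokens_per_word, n, replace = TRUE)
          p$right_token <- sample(corpus$tokens_per_word, n, replace = TRUE)
        }
        p$condition_label <- cond$label
        p$dr_left <- dl
        p$dr_right <- dr_
        per_block <- n %/% n_blocks
        quota <- rep(per_block, n_blocks)
        quota[n_blocks] <- n - per_block * (n_blocks - 1L)
        p$block <- rep(seq_len(n_blocks), times = quota)
        cells[[length(cells) + 1L]] <- p
      }
    }
    trials <- do.call(rbind, cells)
    # seeded permutation within each block
    ord <- order(trials$block, sample.int(nrow(trials)))
    trials <- trials[ord, , drop = FALSE]
    trials$position <- stats::ave(seq_len(nrow(trials)), trials$block,
                                  FUN = seq_along)
    trials$trial_id <- seq_len(nrow(trials))
    rownames(trials) <- NULL
  })

  trials <- trials[, c("trial_id", "block", "position", "family",
                       "left_word", "left_token", "right_word", "right_token",
                       "condition_label", "dr_left", "dr_right")]
  structure(list(trials = trials, seed = as.integer(seed),
                 asym_small_dr_ear = asym_small_dr_ear,
                 n_blocks = as.integer(n_blocks)),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  bt <- table(x$trials$block)
  cat(sprintf("Schedule: %d trials in %d blocks (%s), seed %d, small-DR ear: %s\n",
              nrow(x$trials), x$n_blocks,
              paste(as.integer(bt), collapse = "/"), x$seed,
              x$asym_small_dr_ear))
  invisible(x)
}

#' Write / read a schedule as CSV
#'
#' The CSV holds one row per trial with the schedule metadata (`seed`,
#' `asym_small_dr_ear`, `n_blocks`) stored in `#`-prefixed header comments,
#' so `read_schedule(write_schedule(x, f))` round-trips losslessly.
#'
#' @param schedule A [build_schedule()] result.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%d", schedule$seed),
               sprintf("# asym_small_dr_ear=%s", schedule$asym_small_dr_ear),
               sprintf("# n_blocks=%d", schedule$n_blocks)), con)
  utils::write.csv(schedule$trials, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- sub("^# *", "", hdr)
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  trials <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  structure(list(trials = trials, seed = as.integer(vals[["seed"]]),
                 asym_small_dr_ear = vals[["asym_small_dr_ear"]],
                 n_blocks = as.integer(vals[["n_blocks"]])),
            class = "schedule")
}
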