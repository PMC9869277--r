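clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Synthetic-listener parameters
#'
#' Generative model of a respondent in the dichotic task.  Per-ear word
#' identification follows a logistic function of the ear's dynamic range,
#' anchored at 75 percent correct when DR equals `intelligibility_midpoint`:
#' \eqn{p(DR) = logistic(logit(0.75) + slope (DR - midpoint))}.
#' The probability of a one-word response grows linearly as the mean DR
#' across ears falls: \eqn{p_1 = fusion\_base + fusion\_dr\_gain (100 -
#' \bar{DR})}, clamped to \[0, 1\].  When one word is reported it comes from
#' the attended ear, chosen right with probability
#' \eqn{w = right\_ear\_weight + better\_ear\_gain (DR_R - DR_L)} (clamped).
#' Misidentified words are corrupted toward a same-set neighbor, with
#' liquid-for-cluster (and cluster-for-liquid) substitutions favored.  With
#' probability `lapse` the response is uniform over the 120 legal
#' combinations.
#'
#' @param intelligibility_midpoint DR percent at which per-ear
#'   identification is 75 percent.
#' @param intelligibility_slope Logistic slope per DR percent.
#' @param fusion_base One-word response probability at 100 percent
#'   symmetric DR.
#' @param fusion_dr_gain Increase in one-word probability per percent
#'   decrease in mean DR.
#' @param right_ear_weight Attention weight toward the right ear in
#'   \[0, 1\]; 0.5 is unbiased.
#' @param better_ear_gain Added attention weight per percent of DR
#'   advantage of the right over the left ear.
#' @param lapse Probability of a uniform random legal response.
#' @return Object of class `listener_params`.
#' @export
listener_params <- function(intelligibility_midpoint = 45,
                            intelligibility_slope = 0.08,
                            fusion_base = 0.3, fusion_dr_gain = 0.006,
                            right_ear_weight = 0.55,
                            better_ear_gain = 0.004, lapse = 0.02) {
  p <- list(intelligibility_midpoint = intelligibility_midpoint,
            intelligibility_slope = intelligibility_slope,
            fusion_base = fusion_base, fusion_dr_gain = fusion_dr_gain,
            right_ear_weight = right_ear_weight,
            better_ear_gain = better_ear_gain, lapse = lapse)
  if (p$lapse < 0 || p$lapse > 1 || p$fusion_base < 0 || p$fusion_base > 1 ||
      p$right_ear_weight < 0 || p$right_ear_weight > 1)
    stop("probabilities must lie in [0, 1]")
  structure(p, class = "listener_params")
}

#' @export
print.listener_params <- function(x, ...) {
  cat("Synthetic listener parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Listener presets
#'
#' Two qualitative profiles: `"ynh"` (younger normal-hearing-like: lower
#' lapse, weaker right-ear weighting) and `"onh"` (older normal-hearing-
#' like: more fusion as DR drops, more lapses, stronger right-ear
#' weighting).  These encode qualitative contrasts only, not any measured
#' human values.
#'
#' @param profile `"ynh"` or `"onh"`.
#' @return A [listener_params()] object.
#' @export
listener_preset <- function(profile = c("ynh", "onh")) {
  profile <- match.arg(profile)
  if (profile == "ynh") listener_params()
  else listener_params(intelligibility_midpoint = 48,
                       intelligibility_slope = 0.07, fusion_base = 0.32,
                       fusion_dr_gain = 0.008, right_ear_weight = 0.62,
                       better_ear_gain = 0.004, lapse = 0.05)
}

p_ear_correct <- function(dr, params) {
  stats::plogis(stats::qlogis(0.75) +
                  params$intelligibility_slope *
                  (dr - params$intelligibility_midpoint))
}

# Same-set corruption: liquids attract their cluster, clusters their liquid.
corrupt_word <- function(label, corpus) {
  w <- corpus$words
  row <- w[match(label, w$label), ]
  same <- w[w$set_id == row$set_id & w$label != label, ]
  favored <- NULL
  if (row$onset_class == "liquid") {
    favored <- same$label[same$onset_class == "cluster" &
                            same$liquid == row$liquid]
  } else if (row$onset_class == "cluster") {
    favored <- same$label[same$onset_class == "liquid" &
                            same$liquid == row$liquid]
  }
  if (length(favored) == 1 && stats::runif(1) < 0.5) return(favored)
  sample(same$label, 1)
}

legal_responses <- function(corpus) {
  labs <- corpus$words$label
  pairs <- utils::combn(labs, 2)
  c(as.list(labs),
    lapply(seq_len(ncol(pairs)), function(j) pairs[, j]))
}

#' Simulate one response
#'
#' Draws a response to one trial from the generative model described in
#' [listener_params()], using the current RNG state.
#'
#' @param trial One row of a schedule's `trials` data frame.
#' @param params A [listener_params()] object.
#' @param corpus The corpus.
#' @return Character vector of 1 or 2 word labels.
#' @export
simulate_response <- function(trial, params,
                              corpus = build_default_corpus()) {
  stopifnot(inherits(params, "listener_params"))
  if (stats::runif(1) < params$lapse) {
    resp <- legal_responses(corpus)
    return(resp[[sample.int(length(resp), 1)]])
  }
  dl <- if (is.na(trial$dr_left)) 100 else trial$dr_left
  dr_ <- if (is.na(trial$dr_right)) 100 else trial$dr_right
  heard_l <- if (stats::runif(1) < p_ear_correct(dl, params))
    trial$left_word else corrupt_word(trial$left_word, corpus)
  heard_r <- if (stats::runif(1) < p_ear_correct(dr_, params))
    trial$right_word else corrupt_word(trial$right_word, corpus)
  p_one <- clamp01(params$fusion_base +
                     params$fusion_dr_gain * (100 - (dl + dr_) / 2))
  if (stats::runif(1) < p_one) {
    w_right <- clamp01(params$right_ear_weight +
                         params$better_ear_gain * (dr_ - dl))
    if (stats::runif(1) < w_right) heard_r else heard_l
  } else {
    if (heard_l == heard_r) heard_l else c(heard_l, heard_r)
  }
}

#' Simulate a full experiment
#'
#' One response per schedule trial, deterministic given `seed`.
#'
#' @param schedule A [build_schedule()] result.
#' @param params A [listener_params()] object.
#' @param seed Integer seed.
#' @param corpus The corpus.
#' @return Data frame with columns `trial_id`, `word1`, `word2` (`NA` for
#'   one-word responses).
#' @export
simulate_experiment <- function(schedule, params, seed = 1L,
                                corpus = build_default_corpus()) {
  stopifnot(inherits(schedule, "schedule"))
  tr <- schedule$trials
  withr_seed(as.integer(seed), {
    out <- lapply(seq_len(nrow(tr)), function(i)
      simulate_response(tr[i, ], params, corpus))
  })
  data.frame(trial_id = tr$trial_id,
             word1 = vapply(out, `[`, "", 1),
             word2 = vapply(out, function(w)
               if (length(w) > 1) w[2] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

# Distribution of corrupt_word(label): favored neighbor w.p. 0.5 + 0.5/4,
# the other three same-set words w.p. 0.5/4 each.
corrupt_prob <- function(corpus, label) {
  w <- corpus$words
  row <- w[match(label, w$label), ]
  same <- w$label[w$set_id == row$set_id & w$label != label]
  p <- stats::setNames(rep(0.5 / 4, length(same)), same)
  favored <- character(0)
  if (row$onset_class == "liquid") {
    favored <- w$label[w$set_id == row$set_id & w$onset_class == "cluster" &
                         !is.na(w$liquid) & w$liquid == row$liquid]
  } else if (row$onset_class == "cluster") {
    favored <- w$label[w$set_id == row$set_id & w$onset_class == "liquid" &
                         !is.na(w$liquid) & w$liquid == row$liquid]
  }
  if (length(favored) == 1) p[favored] <- p[favored] + 0.5
  p
}

# Coefficients of P(heard_left == heard_right) as a bilinear form in the
# per-ear accuracies: a*pL*pR + b*pL*(1-pR) + c*(1-pL)*pR + d*(1-pL)(1-pR),
# averaged over a family's trial pairings (parameter-free constants).
collision_coefs <- function(corpus, trials) {
  co <- t(vapply(seq_len(nrow(trials)), function(i) {
    L <- trials$left_word[i]; R <- trials$right_word[i]
    pl <- corrupt_prob(corpus, L); pr <- corrupt_prob(corpus, R)
    shared <- intersect(names(pl), names(pr))
    c(a = as.numeric(L == R),
      b = if (L %in% names(pr)) unname(pr[L]) else 0,
      c = if (R %in% names(pl)) unname(pl[R]) else 0,
      d = sum(pl[shared] * pr[shared]))
  }, numeric(4)))
  colMeans(co)
}

# Per-condition sufficient statistics for the likelihood: same-word
# correctness, the different-vowel response-type multinomial, and one-word
# counts (with collision coefficients) for every family.
fit_statistics <- function(responses, schedule,
                           corpus = build_default_corpus()) {
  scored <- score_trials(schedule, responses, corpus)
  one_cond <- scored[scored$condition_label ==
                       scored$condition_label[1], ]
  coefs <- list(
    sw = collision_coefs(corpus,
                         one_cond[one_cond$family == "same_word", ]),
    rh = collision_coefs(corpus,
                         one_cond[one_cond$family %in%
                                    c("fusion", "other_rhyme"), ]))
  conds <- unique(scored$condition_label)
  stats_df <- do.call(rbind, lapply(conds, function(cl) {
    d <- scored[scored$condition_label == cl, ]
    dl <- d$dr_left[1]; dr_ <- d$dr_right[1]
    if (is.na(dl)) { dl <- 100; dr_ <- 100 }
    sw <- d[d$family == "same_word", ]
    dv <- d[d$family == "different_vowel", ]
    rh <- d[d$family %in% c("fusion", "other_rhyme"), ]
    data.frame(condition_label = cl, dr_left = dl, dr_right = dr_,
               sw_n = nrow(sw), sw_k = sum(sw$correct_same_word),
               sw_one = sum(sw$n_words == 1),
               rh_n = nrow(rh), rh_one = sum(rh$n_words == 1),
               dv_two = sum(dv$n_words == 2),
               dv_left = sum(dv$n_words == 1 & dv$ear_attribution == "left"),
               dv_right = sum(dv$n_words == 1 &
                                dv$ear_attribution == "right"),
               dv_neither = sum(dv$n_words == 1 &
                                  dv$ear_attribution == "neither"),
               stringsAsFactors = FALSE)
  }))
  attr(stats_df, "collision") <- coefs
  stats_df
}

listener_loglik <- function(theta, stats_df, fixed) {
  p <- fixed
  p$right_ear_weight <- theta[["right_ear_weight"]]
  p$fusion_base <- theta[["fusion_base"]]
  p$fusion_dr_gain <- theta[["fusion_dr_gain"]]
  p$intelligibility_midpoint <- theta[["intelligibility_midpoint"]]
  lapse <- p$lapse
  coefs <- attr(stats_df, "collision")
  collide <- function(co, pl, pr)
    co[["a"]] * pl * pr + co[["b"]] * pl * (1 - pr) +
      co[["c"]] * (1 - pl) * pr + co[["d"]] * (1 - pl) * (1 - pr)
  ll <- 0
  eps <- 1e-12
  for (i in seq_len(nrow(stats_df))) {
    s <- stats_df[i, ]
    pl <- p_ear_correct(s$dr_left, p)
    pr <- p_ear_correct(s$dr_right, p)
    p1 <- clamp01(p$fusion_base +
                    p$fusion_dr_gain * (100 - (s$dr_left + s$dr_right) / 2))
    wr <- clamp01(p$right_ear_weight +
                    p$better_ear_gain * (s$dr_right - s$dr_left))
    pc <- (1 - lapse) * (p1 * (wr * pr + (1 - wr) * pl) +
                           (1 - p1) * pl * pr) + lapse / 120
    ll <- ll + s$sw_k * log(pc + eps) +
      (s$sw_n - s$sw_k) * log(1 - pc + eps)
    probs <- c(two = (1 - lapse) * (1 - p1) + lapse * 105 / 120,
               left = (1 - lapse) * p1 * (1 - wr) + lapse / 24,
               right = (1 - lapse) * p1 * wr + lapse / 24,
               neither = lapse / 24)
    counts <- c(s$dv_two, s$dv_left, s$dv_right, s$dv_neither)
    ll <- ll + sum(counts * log(probs + eps))
    # one-word counts in the same-word and rhyming families also carry
    # information on the fusion probability (heard-word collisions via the
    # corruption channel make some non-fused responses one word)
    if (!is.null(coefs)) {
      p1_sw <- (1 - lapse) * (p1 + (1 - p1) * collide(coefs$sw, pl, pr)) +
        lapse * 15 / 120
      ll <- ll + s$sw_one * log(p1_sw + eps) +
        (s$sw_n - s$sw_one) * log(1 - p1_sw + eps)
      p1_rh <- (1 - lapse) * (p1 + (1 - p1) * collide(coefs$rh, pl, pr)) +
        lapse * 15 / 120
      ll <- ll + s$rh_one * log(p1_rh + eps) +
        (s$rh_n - s$rh_one) * log(1 - p1_rh + eps)
    }
  }
  ll
}

#' Fit listener parameters by maximum likelihood
#'
#' Recovers `right_ear_weight`, `fusion_base`, `fusion_dr_gain` and
#' `intelligibility_midpoint` from a response table by maximizing the model
#' likelihood of per-condition summaries: same-word correctness (Bernoulli),
#' the different-vowel response type (two-word / one-word attributed left /
#' right / neither; multinomial), and the one-word response counts of every
#' family, whose heard-word collision probabilities are computed exactly
#' from the corruption channel.  A coarse grid search seeds a Nelder-Mead
#' refinement.  The remaining parameters (`lapse`, `intelligibility_slope`,
#' `better_ear_gain`) are held at the values in `fixed`.
#'
#' @param responses Data frame from [simulate_experiment()] (columns
#'   `trial_id`, `word1`, `word2`).
#' @param schedule The schedule the responses answer.
#' @param grid Named list of candidate values for the four fitted
#'   parameters; defaults give a coarse first pass.
#' @param fixed A [listener_params()] holding the non-fitted parameters.
#' @param corpus The corpus.
#' @return Object of class `listener_fit`: list with `estimate` (named
#'   vector), `logLik`, `grid` (data frame of the grid evaluations), and
#'   `fixed`.
#' @export
fit_listener_params <- function(responses, schedule, grid = NULL,
                                fixed = listener_params(),
                                corpus = build_default_corpus()) {
  if (is.null(responses) || nrow(responses) == 0) stop("no responses to fit")
  stats_df <- fit_statistics(responses, schedule, corpus)
  if (is.null(grid))
    grid <- list(right_ear_weight = seq(0.1, 0.9, by = 0.1),
                 fusion_base = seq(0.05, 0.8, by = 0.1),
                 fusion_dr_gain = c(0, 0.003, 0.006, 0.009, 0.012),
                 intelligibility_midpoint = seq(30, 60, by = 10))
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  g$logLik <- vapply(seq_len(nrow(g)), function(i)
    listener_loglik(unlist(g[i, c("right_ear_weight", "fusion_base",
                                  "fusion_dr_gain",
                                  "intelligibility_midpoint")]),
                    stats_df, fixed), numeric(1))
  best <- unlist(g[which.max(g$logLik),
                   c("right_ear_weight", "fusion_base", "fusion_dr_gain",
                     "intelligibility_midpoint")])
  opt <- stats::optim(best, function(th) {
    th <- stats::setNames(th, names(best))
    if (th[["right_ear_weight"]] < 0 || th[["right_ear_weight"]] > 1 ||
        th[["fusion_base"]] < 0 || th[["fusion_base"]] > 1 ||
        th[["fusion_dr_gain"]] < 0) return(-1e12)
    listener_loglik(th, stats_df, fixed)
  }, control = list(fnscale = -1, maxit = 500))
  structure(list(estimate = stats::setNames(opt$par, names(best)),
                 logLik = opt$value, grid = g, fixed = fixed),
            class = "listener_fit")
}

#' @export
print.listener_fit <- function(x, ...) {
  cat("Listener model fit (maximum likelihood)\n")
  for (nm in names(x$estimate))
    cat(sprintf("  %-26s %.4f\n", nm, x$estimate[[nm]]))
  cat(sprintf("  log-likelihood          %.2f\n", x$logLik))
  invisible(x)
}

#' @export
coef.listener_fit <- function(object, ...) object$estimate

#' @export
logLik.listener_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$estimate),
            class = "logLik")
}
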