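corp <- build_default_corpus()
mk_trial <- function(family, left, right, cond = "60:60",
                     dl = 60, dr_ = 60) {
  data.frame(trial_id = 1L, family = family, left_word = left,
             right_word = right, condition_label = cond, dr_left = dl,
             dr_right = dr_, stringsAsFactors = FALSE)
}

test_that("same-word scoring requires a single exact match", {
  tr <- mk_trial("same_word", "bed", "bed")
  expect_true(score_same_word(tr, "bed", corp)$correct_same_word)
  expect_false(score_same_word(tr, c("bed", "led"), corp)$correct_same_word)
  expect_false(score_same_word(tr, "bled", corp)$correct_same_word)
  expect_error(score_same_word(mk_trial("fusion", "bed", "led"), "bed",
                               corp))
})

test_that("different-vowel scoring counts at-least-one and attributes ears", {
  tr <- mk_trial("different_vowel", "bed", "pay")
  s <- score_different_vowel(tr, c("bed", "pay"), corp)
  expect_true(s$at_least_one_correct)
  expect_equal(s$n_words, 2)
  # wrong word, vowel of the left set: attributed left
  s2 <- score_different_vowel(tr, "led", corp)
  expect_false(s2$at_least_one_correct)
  expect_equal(s2$ear_attribution, "left")
  s3 <- score_different_vowel(tr, "go", corp)
  expect_equal(s3$ear_attribution, "neither")
  s4 <- score_different_vowel(tr, "ray", corp)
  expect_equal(s4$ear_attribution, "right")
  # accuracy invariant to word order in the response
  sa <- score_different_vowel(tr, c("pay", "bed"), corp)
  expect_equal(sa$at_least_one_correct, s$at_least_one_correct)
})

test_that("the fusion taxonomy classifies the worked examples", {
  tr <- mk_trial("fusion", "bed", "led")
  expect_equal(classify_fusion_response(tr, c("bed", "led"), corp), "ideal")
  expect_equal(classify_fusion_response(tr, "bled", corp), "fused")
  expect_equal(classify_fusion_response(tr, "red", corp), "interference")
  expect_equal(classify_fusion_response(tr, c("led", "go"), corp),
               "biased_right")
  # cluster word plus one presented word: only that ear's word is correct
  expect_equal(classify_fusion_response(tr, c("bled", "bed"), corp),
               "biased_left")
  # cluster plus an unrelated word is not a one-word fused response
  expect_equal(classify_fusion_response(tr, c("bled", "go"), corp),
               "interference")
  # other-rhyme trials use the taxonomy without a fused target
  tro <- mk_trial("other_rhyme", "led", "red")
  expect_equal(classify_fusion_response(tro, c("led", "red"), corp), "ideal")
  expect_equal(classify_fusion_response(tro, "bled", corp), "interference")
})

test_that("exactly one category fires for every legal response", {
  responses <- all_legal_responses(corp)
  orderings <- all_fusible_orderings(corp)
  expect_length(responses, 120)
  expect_length(orderings, 12)
  cats <- c("ideal", "fused", "biased_left", "biased_right", "interference")
  for (ord in orderings) {
    tr <- mk_trial("fusion", ord[1], ord[2])
    target <- dichovoc:::fusion_target(corp, ord[1], ord[2])
    got <- vapply(responses, function(r)
      classify_fusion_response(tr, r, corp), "")
    want <- vapply(responses, function(r)
      oracle_fusion_category(ord[1], ord[2], r, target), "")
    expect_true(all(got %in% cats))
    expect_equal(got, want)
  }
})

sched <- build_schedule(corp, seed = 5)

test_that("a perfect responder scores perfectly everywhere", {
  perfect <- respond_all(sched, function(tr) {
    if (tr$left_word == tr$right_word) tr$left_word
    else c(tr$left_word, tr$right_word)
  })
  scored <- score_trials(sched, perfect, corp)
  agg <- aggregate_scores(scored, n_boot = 50, seed = 2)
  expect_true(all(agg$summary$accuracy == 1))
  expect_true(all(agg$summary$acc_lo == 1 & agg$summary$acc_hi == 1))
  ideal <- agg$categories[agg$categories$category == "ideal", ]
  expect_true(all(ideal$prop == 1))
  # category frequencies partition each cell
  tot <- tapply(agg$categories$prop,
                paste(agg$categories$condition_label,
                      agg$categories$family), sum)
  expect_true(all(abs(tot - 1) < 1e-12))
  cm <- vowel_confusions(scored, corp)
  expect_true(all(rowSums(cm) == table(vapply(seq_len(nrow(scored)),
    function(i) {
      v <- corp$words$vowel[match(c(scored$left_word[i],
                                    scored$right_word[i]),
                                  corp$words$label)]
      paste(sort(unique(v)), collapse = "+")
    }, ""))[rownames(cm)]))
  # perfect same-word responses give a diagonal single-vowel block
  sw <- scored[scored$family == "same_word", ]
  cmsw <- vowel_confusions(sw, corp)
  expect_true(all(cmsw[upper.tri(cmsw) | lower.tri(cmsw)] == 0))
})

test_that("bootstrap aggregation is seed-reproducible", {
  noisy <- respond_all(sched, function(tr) {
    if (tr$trial_id %% 3 == 0) "go" else tr$left_word
  })
  scored <- score_trials(sched, noisy, corp)
  a1 <- aggregate_scores(scored, n_boot = 100, seed = 7)
  a2 <- aggregate_scores(scored, n_boot = 100, seed = 7)
  expect_identical(a1, a2)
  # same-word accuracy can never exceed the one-word proportion
  sw <- a1$summary[a1$summary$family == "same_word", ]
  expect_true(all(sw$accuracy <= sw$p_one_word + 1e-12))
})

test_that("ear advantage reflects attribution and better/worse recoding", {
  right_only <- respond_all(sched, function(tr) tr$right_word)
  scored <- score_trials(sched, right_only, corp)
  ea <- ear_advantage(scored, "left_right", "different_vowel")
  expect_true(all(ea$prop_right == 1))
  # small-DR ear is left, so better = right: all responses are better-ear
  bw <- ear_advantage(scored, "better_worse", "different_vowel",
                      conditions = c("100:60", "100:40", "60:40"))
  expect_true(all(bw$prop_better == 1))
  expect_error(ear_advantage(scored, "better_worse", "different_vowel",
                             conditions = "60:60"))
  # fusion-family attribution uses word identity
  eaf <- ear_advantage(scored, "left_right", "fusion")
  expect_true(all(eaf$prop_right == 1))
})

test_that("liquid-only proportions count pure liquid responses", {
  tr <- mk_trial("fusion", "bed", "led")
  scored1 <- score_trials(
    structure(list(trials = cbind(tr,
      data.frame(block = 1, position = 1, left_token = 1, right_token = 2)),
      seed = 1L, asym_small_dr_ear = "left", n_blocks = 1L),
      class = "schedule"),
    make_response_df(1L, "led"), corp)
  expect_true(scored1$liquid_only)
  scored2 <- score_trials(
    structure(list(trials = cbind(tr,
      data.frame(block = 1, position = 1, left_token = 1, right_token = 2)),
      seed = 1L, asym_small_dr_ear = "left", n_blocks = 1L),
      class = "schedule"),
    make_response_df(1L, "bled"), corp)
  expect_false(scored2$liquid_only)
  # uniform single-word guessing: expected liquid-only proportion is 6/15
  labs <- rep(corp$words$label, length.out = nrow(sched$trials))
  uniform <- make_response_df(sched$trials$trial_id, labs)
  scored <- score_trials(sched, uniform, corp)
  lp <- liquid_only_proportion(scored, "same_word")
  expect_equal(mean(lp$prop_liquid_only), 0.4, tolerance = 0.05)
})
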