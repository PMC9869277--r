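corp <- build_default_corpus()
sched <- build_schedule(corp, seed = 3)

test_that("a pure-lapse listener responds uniformly over the 120 combinations", {
  p <- listener_params(lapse = 1)
  tr <- sched$trials[sched$trials$family == "fusion", ][1, ]
  n <- 12000
  set.seed(99)
  keys <- vapply(seq_len(n), function(i)
    paste(sort(simulate_response(tr, p, corp)), collapse = "+"), "")
  tab <- table(keys)
  expect_length(tab, 120)
  gof <- suppressWarnings(chisq.test(as.numeric(tab),
                                     p = rep(1 / 120, 120)))
  expect_gt(gof$p.value, 0.01)
})

test_that("a perfect non-fusing listener reports both words correctly", {
  p <- listener_params(intelligibility_midpoint = 0,
                       intelligibility_slope = 5, fusion_base = 0,
                       fusion_dr_gain = 0, lapse = 0)
  resp <- simulate_experiment(sched, p, seed = 4)
  scored <- score_trials(sched, resp, corp)
  dv <- scored[scored$family == "different_vowel", ]
  expect_true(all(dv$at_least_one_correct))
  expect_true(all(dv$n_words == 2))
})

test_that("full right-ear weighting with certain fusion reports only the right ear", {
  p <- listener_params(intelligibility_midpoint = 0,
                       intelligibility_slope = 5, fusion_base = 1,
                       fusion_dr_gain = 0, right_ear_weight = 1,
                       better_ear_gain = 0, lapse = 0)
  resp <- simulate_experiment(sched, p, seed = 6)
  scored <- score_trials(sched, resp, corp)
  dv <- scored[scored$family == "different_vowel", ]
  expect_true(all(dv$n_words == 1))
  expect_true(all(dv$ear_attribution == "right"))
})

test_that("simulated experiments are complete and seed-deterministic", {
  p <- listener_preset("ynh")
  r1 <- simulate_experiment(sched, p, seed = 10)
  expect_equal(nrow(r1), 3192)
  expect_identical(r1, simulate_experiment(sched, p, seed = 10))
  expect_false(identical(r1, simulate_experiment(sched, p, seed = 11)))
  scored <- score_trials(sched, r1, corp)
  agg <- aggregate_scores(scored, n_boot = 20, seed = 1)
  tot <- tapply(agg$categories$prop,
                paste(agg$categories$condition_label,
                      agg$categories$family), sum)
  expect_true(all(abs(tot - 1) < 1e-12))
})

test_that("lower symmetric dynamic range never helps same-word accuracy", {
  p <- listener_preset("ynh")
  accs <- vapply(c(100, 70, 40, 20), function(dr) {
    tr <- data.frame(trial_id = 1L, family = "same_word",
                     left_word = "pay", right_word = "pay",
                     condition_label = "x", dr_left = dr, dr_right = dr)
    set.seed(1000 + dr)
    mean(vapply(1:3000, function(i) {
      w <- simulate_response(tr, p, corp)
      length(w) == 1 && w == "pay"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(accs) < 0.02))
})

test_that("asymmetry with positive better-ear gain steers attribution to the better ear", {
  p <- listener_params(fusion_base = 1, fusion_dr_gain = 0,
                       right_ear_weight = 0.5, better_ear_gain = 0.004,
                       lapse = 0)
  resp <- simulate_experiment(sched, p, seed = 12)
  scored <- score_trials(sched, resp, corp)
  bw <- ear_advantage(scored, "better_worse", "different_vowel",
                      conditions = c("100:40"))
  # delta DR = 60 -> w_right = 0.5 + 0.004*60 = 0.74 toward the better ear
  expect_gt(bw$prop_better, 0.6)
})

test_that("parameters are recoverable from one simulated experiment", {
  truth <- listener_params(right_ear_weight = 0.7, fusion_base = 0.3)
  resp <- simulate_experiment(sched, truth, seed = 21)
  fit <- fit_listener_params(resp, sched, fixed = truth)
  expect_lt(abs(coef(fit)[["right_ear_weight"]] - 0.7), 0.05)
  expect_lt(abs(coef(fit)[["fusion_base"]] - 0.3), 0.05)
  expect_s3_class(fit, "listener_fit")
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_error(fit_listener_params(resp[0, ], sched))
})

test_that("lapse-only data prefer the flat model over structured alternatives", {
  p_flat <- listener_params(lapse = 1)
  resp <- simulate_experiment(sched, p_flat, seed = 31)
  stats_df <- dichovoc:::fit_statistics(resp, sched, corp)
  # evaluate both candidate structures under a small fixed lapse so the
  # structural parameters actually shape the likelihood
  fixed <- listener_params(lapse = 0.05)
  flat_theta <- c(right_ear_weight = 0.5, fusion_base = 0.125,
                  fusion_dr_gain = 0, intelligibility_midpoint = 45)
  structured_theta <- c(right_ear_weight = 0.9, fusion_base = 0.8,
                        fusion_dr_gain = 0, intelligibility_midpoint = 45)
  ll_flat <- dichovoc:::listener_loglik(flat_theta, stats_df, fixed)
  ll_struct <- dichovoc:::listener_loglik(structured_theta, stats_df, fixed)
  expect_gt(ll_flat, ll_struct)
})
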