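test_that("confusion counts match an exhaustive tally", {
  disc <- c(rep(TRUE, 80), rep(FALSE, 220))
  all80 <- confusion(1:80, disc)
  expect_equal(unclass(all80)[c("TP", "FP", "FN", "TN")],
               list(TP = 80L, FP = 0L, FN = 0L, TN = 220L))
  none <- confusion(integer(0), disc)
  expect_equal(none$TP, 0); expect_equal(none$FN, 80)
  set.seed(1)
  sel <- sample(300, 100)
  cc <- confusion(sel, disc)
  expect_equal(cc$TP, sum(sel <= 80))
  expect_equal(cc$FP, sum(sel > 80))
  expect_equal(cc$TP + cc$FN, 80)
  expect_equal(cc$FP + cc$TN, 220)
  expect_error(confusion(c(1, 301), disc), "index error")
})

test_that("recall, precision and F1 match their printed definitions", {
  c1 <- confusion(1:77, c(rep(TRUE, 80), rep(FALSE, 100)))
  pr <- prf_scores(c1)
  expect_equal(pr[["recall"]], 77 / 80)
  expect_equal(pr[["recall"]], 0.9625)
  c2 <- structure(list(TP = 77L, FP = 117L, FN = 3L, TN = 2803L),
                  class = "confusion")
  pr2 <- prf_scores(c2)
  expect_equal(pr2[["precision"]], 77 / 194)
  expect_equal(pr2[["precision"]], 0.3969, tolerance = 1e-4)
  expect_equal(pr2[["f1"]],
               2 * pr2[["precision"]] * pr2[["recall"]] /
                 (pr2[["precision"]] + pr2[["recall"]]))
  # recall = precision = p gives F1 = p for any beta = 1 grid point
  c3 <- structure(list(TP = 30L, FP = 10L, FN = 10L, TN = 50L),
                  class = "confusion")
  pr3 <- prf_scores(c3)
  expect_equal(pr3[["f1"]], 0.75)
  # undefined cases warn and return NA
  c4 <- structure(list(TP = 0L, FP = 0L, FN = 5L, TN = 10L), class = "confusion")
  expect_warning(pr4 <- prf_scores(c4), "precision undefined")
  expect_true(is.na(pr4[["precision"]]))
})

test_that("the variable-selection ROC equals the Mann-Whitney identity", {
  # perfect ranking
  st <- fake_vip_stats(c(5:1) / 1, rep(0, 5))
  perfect <- vs_roc(st, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(perfect$auvsc, 1)
  # random scores: AUVSC equals the rank-sum statistic, ties counted half
  set.seed(2)
  stats <- fake_vip_stats(round(rnorm(60), 1), abs(round(rnorm(60, 0, 0.2), 1)))
  truth <- rbinom(60, 1, 0.4) == 1
  roc <- vs_roc(stats, truth)
  score <- stats$vip_mean - stats$vip_sd
  mw <- mean(outer(score[truth], score[!truth],
                   function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc$auvsc, mw, tolerance = 1e-12)
  # curve endpoints
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  expect_error(vs_roc(stats, rep(TRUE, 60)), "undefined")
  # truth-independent rankings average near one half
  set.seed(3)
  nulls <- replicate(40, {
    s <- fake_vip_stats(rnorm(50), rep(0, 50))
    vs_roc(s, rbinom(50, 1, 0.5) == 1)$auvsc
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
})

test_that("permutation test calibrates against unit-level label exchange", {
  # strong group signal: observed statistic beats every permutation
  cfg <- sim_config(n_units_per_group = 5, n_variables = 30,
                    n_discriminating = 10, sigma_b = 0.1, seed = 4)
  sim <- simulate_dataset(cfg)
  pt <- permutation_test(sim$table, model_spec(3), n_perm = 19, seed = 5)
  expect_equal(pt$p_value, 1 / 20)
  expect_length(pt$permuted, 19)
  # determinism
  pt2 <- permutation_test(sim$table, model_spec(3), n_perm = 19, seed = 5)
  expect_equal(pt$p_value, pt2$p_value)
  expect_equal(pt$permuted, pt2$permuted)
  expect_error(permutation_test(sim$table, model_spec(3), n_perm = 0), "config")
})

test_that("t-test flagging detects overwhelming effects and respects alpha", {
  tbl <- toy_table(S_per_group = 6, J = 5, seed = 6)
  shift <- tbl$samples$group == "intervention" & tbl$samples$time == 2
  tbl$X[shift, 2] <- tbl$X[shift, 2] + 8
  flags <- ttest_flag(tbl)
  expect_true(flags[2])
  expect_equal(ttest_flag(tbl, alpha = 0), rep(FALSE, 5))
  # type-I behaviour on null variables: one test per time point, min over 4
  set.seed(7)
  nulls <- replicate(30, {
    t0 <- toy_table(S_per_group = 15, J = 20, seed = sample.int(1e6, 1))
    mean(ttest_flag(t0))
  })
  # P(min p < .05 over 4 independent tests) = 1 - 0.95^4, about 0.185
  expect_lt(abs(mean(nulls) - (1 - 0.95^4)), 0.05)
})

test_that("the benchmark harness emits the full metric layout deterministically", {
  cfg <- sim_config(n_units_per_group = 6, n_variables = 100,
                    n_discriminating = 12, seed = 8)
  bm <- run_benchmark(cfg, models = c(2, 3, 4), n_repeats = 1, B = 15,
                      seed = 9, A_max = 4)
  expect_s3_class(bm, "benchmark_result")
  expect_equal(nrow(bm$per_repeat), 3)
  expect_true(all(c("model", "n_latent", "n_selected", "TP", "FP", "FN",
                    "recall", "precision", "f1", "auvsc", "q2", "auc") %in%
                    names(bm$per_repeat)))
  ok <- is.finite(bm$per_repeat$auvsc)
  expect_true(all(bm$per_repeat$auvsc[ok] >= 0 & bm$per_repeat$auvsc[ok] <= 1))
  bm2 <- run_benchmark(cfg, models = c(2, 3, 4), n_repeats = 1, B = 15,
                       seed = 9, A_max = 4)
  expect_identical(bm$per_repeat, bm2$per_repeat)
  # model 2 ignores the group labels: its classification is near chance
  expect_lt(bm$per_repeat$auc[bm$per_repeat$model == 2], 0.85)
  expect_gt(bm$per_repeat$auc[bm$per_repeat$model == 2], 0.15)
})
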