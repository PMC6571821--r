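test_that("VIP reduces to known values for single-component models", {
  # uniform weights: every VIP is 1
  fit <- structure(list(weights = matrix(0.5, 4, 1), ssy = 1), class = "bipls")
  expect_equal(vip(fit), rep(1, 4))
  # all weight on variable 1 with J = 4: VIP = (2, 0, 0, 0)
  fit2 <- structure(list(weights = matrix(c(1, 0, 0, 0), 4, 1), ssy = 2),
                    class = "bipls")
  expect_equal(vip(fit2), c(2, 0, 0, 0))
  # single-component trilinear model: VIP_j = sqrt(J) |wJ_j|
  w <- c(0.8, -0.6)
  ft <- structure(list(WJ = matrix(w, 2, 1), ssy = 3), class = "tripls_model")
  expect_equal(vip(ft), sqrt(2) * abs(w))
  # zero explained variance is degenerate
  fit0 <- structure(list(weights = matrix(0.5, 4, 1), ssy = 0), class = "bipls")
  expect_error(vip(fit0), "degenerate")
})

test_that("sum of squared VIPs equals J on real fits of both families", {
  set.seed(1)
  X <- scale(matrix(rnorm(20 * 12), 20, 12))
  y <- rnorm(20)
  fb <- fit_pls(X, y, 4)
  expect_equal(sum(vip(fb)^2), 12, tolerance = 1e-6)

  cube <- random_cube(Sn = 8, J = 7, Tn = 4, seed = 2)
  set.seed(3); yc <- rnorm(8)
  ft <- fit_npls1(cube, yc, 3)
  expect_equal(sum(vip(ft)^2), 7, tolerance = 1e-6)
  Y <- cbind(yc, rnorm(8))
  ft2 <- fit_npls2(cube, Y, 2)
  expect_equal(sum(vip(ft2)^2), 7, tolerance = 1e-6)
})

test_that("balanced bootstrap gives every unit the exact target frequency", {
  sets <- balanced_bootstrap_indices(3, 2, seed = 1)
  expect_equal(length(sets), 2)
  expect_equal(unname(table(unlist(sets))), rep(2L, 3), ignore_attr = TRUE)
  # exact balance at B = 200, n = 10
  sets200 <- balanced_bootstrap_indices(10, 200, seed = 2)
  expect_true(all(vapply(sets200, length, 0L) == 10))
  expect_equal(unname(table(factor(unlist(sets200), levels = 1:10))),
               rep(200L, 10), ignore_attr = TRUE)
  # determinism
  expect_identical(balanced_bootstrap_indices(5, 4, seed = 7),
                   balanced_bootstrap_indices(5, 4, seed = 7))
})

test_that("bootstrap_vip is reproducible and degenerates gracefully at B = 1", {
  tbl <- toy_table(S_per_group = 3, J = 8, seed = 4)
  spec <- model_spec(1)
  st1 <- bootstrap_vip(tbl, spec, A = 1, B = 1, seed = 5)
  expect_equal(st1$vip_sd, rep(0, 8))
  expect_equal(sum(st1$vip_mean^2), 8, tolerance = 1e-6)
  stA <- bootstrap_vip(tbl, spec, A = 2, B = 20, seed = 6)
  stB <- bootstrap_vip(tbl, spec, A = 2, B = 20, seed = 6)
  expect_identical(stA, stB)
  expect_equal(sort(stA$rank), 1:8)
})

test_that("bootstrapped VIP ranks a simulated discriminating variable above noise", {
  wins <- replicate(25, {
    cfg <- sim_config(n_units_per_group = 5, n_variables = 40,
                      n_discriminating = 6, sigma_b = 0.2,
                      seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    st <- bootstrap_vip(sim$table, model_spec(3), A = 2, B = 30,
                        seed = sample.int(1e6, 1))
    noise <- sim$truth$class == "h"
    mean(st$vip_mean[sim$truth$discriminating]) > mean(st$vip_mean[noise])
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the VIP selection rule is strict at the one-sigma boundary", {
  st <- fake_vip_stats(c(1.5, 1.5, 0.9, 2.0), c(0.4, 0.5, 0.0, 0.2))
  expect_equal(select_variables(st), c(1, 4))   # 1.1 > 1; boundary 1.0 excluded
  # raising the threshold never adds variables
  for (thr in c(0.5, 1, 1.5, 2)) {
    sel_lo <- select_variables(st, threshold = thr)
    sel_hi <- select_variables(st, threshold = thr + 0.3)
    expect_true(all(sel_hi %in% sel_lo))
  }
})

test_that("loading-weight selection uses the scaled first-component weight", {
  # uniform weights give statistic exactly 1: nothing passes the strict rule
  cube <- rank1_cube(Sn = 6, J = 4, Tn = 3, seed = 8)
  cube$cube$X3 <- cube$cube$X3 * 0
  for (s in 1:6) cube$cube$X3[s, , ] <-
      cube$t0[s] * tcrossprod(rep(0.5, 4), c(1, 0, 0) / 1)
  fit <- fit_npls1(cube$cube, cube$t0, 1)
  expect_equal(tripls:::loading_weight_stat(fit, 1), rep(1, 4),
               tolerance = 1e-8)

  # a dominant variable in a rank-1 simulation is selected
  tbl <- toy_table(S_per_group = 4, J = 6, seed = 9)
  tbl$X[, 1] <- tbl$X[, 1] +
    5 * (tbl$samples$group == "intervention") * (tbl$samples$time %in% c(2, 4))
  st <- bootstrap_vip(tbl, model_spec(3), A = 1, B = 30, seed = 10,
                      rule = "loading_weight")
  expect_true(1 %in% select_by_loading_weight(st))
  # the rule guard rejects VIP-rule stats
  stv <- fake_vip_stats(c(2, 0.5), c(0.1, 0.1))
  expect_error(select_by_loading_weight(stv), "loading_weight")

  # for single-component models the statistic agrees with the VIP definition
  sc <- autoscale_bilinear(tbl$X)
  y3 <- make_dummy_y(tbl, model_spec(3), response_design())
  f1 <- fit_pls(sc$X, y3, 1)
  expect_equal(tripls:::loading_weight_stat(f1, 1), vip(f1), tolerance = 1e-10)
})
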