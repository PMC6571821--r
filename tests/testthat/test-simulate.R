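test_that("mean_curve follows c + a t^alpha exp(-beta t)", {
  expect_equal(mean_curve(2, 3, 1, 0.5, 0), 2)        # baseline at t = 0
  expect_equal(mean_curve(2, 0, 1.5, 0.5, c(0, 2, 24)), rep(2, 3))  # flat
  # calculus oracle: argmax at alpha / beta for c = 0
  tgrid <- seq(0.01, 30, by = 0.001)
  mu <- mean_curve(0, 1, 1.4, 0.6, tgrid)
  expect_equal(tgrid[which.max(mu)], 1.4 / 0.6, tolerance = 1e-2)
  expect_error(mean_curve(1, 1, -1, 0.5, c(0, 2)), "domain error")
  expect_error(mean_curve(1, 1, 1, -0.5, c(0, 2)), "domain error")
})

test_that("subject random terms match their stated covariance structures", {
  cfg <- sim_config(n_units_per_group = 2, n_variables = 10,
                    n_discriminating = 2, sigma_b = 0.4, sigma_w = 0.3,
                    rho = 0.6, sigma_e = 0.2)
  tr <- draw_subject_terms(cfg, n = 10000, seed = 1)
  # b: constant within subject, variance sigma_b^2, all-ones covariance
  expect_equal(max(abs(tr$b - tr$b[, 1])), 0)
  Cb <- cov(tr$b)
  expect_lt(max(abs(Cb - 0.16)), 3 * 0.16 * sqrt(2 / 10000) * 3)
  # w: AR(1) with lag-1 correlation rho
  Cw <- cor(tr$w)
  expect_equal(Cw[1, 2], 0.6, tolerance = 0.03)
  expect_equal(Cw[1, 3], 0.36, tolerance = 0.04)
  expect_equal(apply(tr$w, 2, sd), rep(0.3, 4), tolerance = 0.01)
  # e: i.i.d.
  Ce <- cor(tr$e)
  expect_lt(max(abs(Ce[upper.tri(Ce)])), 0.04)
  # rho = 0 gives uncorrelated w
  cfg0 <- sim_config(n_units_per_group = 2, n_variables = 10,
                     n_discriminating = 2, rho = 0)
  tr0 <- draw_subject_terms(cfg0, n = 8000, seed = 2)
  C0 <- cor(tr0$w)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.04)
  expect_error(sim_config(rho = 1), "rho")
})

test_that("simulated variables reduce to their mean curves without noise", {
  cfg <- sim_config(n_units_per_group = 4, n_variables = 10,
                    n_discriminating = 2, sigma_b = 0, sigma_w = 0, sigma_e = 0,
                    seed = 3)
  sv <- simulate_variable("a", cfg, seed = 4)
  tr <- sv$truth
  mu_int <- mean_curve(tr$c, tr$a_int, tr$alpha_int, tr$beta_int, cfg$times)
  for (s in 1:4) expect_equal(sv$intervention[s, ], mu_int, tolerance = 1e-12)
  # flat class h: constant at baseline across time
  svh <- simulate_variable("h", cfg, seed = 5)
  expect_equal(svh$control, matrix(svh$truth$c, 4, 4), tolerance = 1e-12)
  expect_equal(svh$intervention, svh$control)
})

test_that("the subject average converges to the mean curve", {
  cfg <- sim_config(n_units_per_group = 1000, n_variables = 10,
                    n_discriminating = 2, seed = 6)
  sv <- simulate_variable("b", cfg, seed = 7)
  tr <- sv$truth
  mu <- mean_curve(tr$c, tr$a_int, tr$alpha_int, tr$beta_int, cfg$times)
  se <- apply(sv$intervention, 2, sd) / sqrt(1000)
  expect_true(all(abs(colMeans(sv$intervention) - mu) < 3 * se + 1e-12))
})

test_that("simulate_dataset realizes the configured design exactly", {
  cfg <- sim_config(n_units_per_group = 3, n_variables = 60,
                    n_discriminating = 12, seed = 8)
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$cube$X3), c(6, 60, 4))
  expect_equal(nrow(sim$table$X), 24)
  expect_equal(sum(sim$truth$discriminating), 12)
  expect_equal(sort(unique(sim$truth$class[sim$truth$discriminating])),
               letters[1:6])
  # determinism
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim$cube$X3, sim2$cube$X3)
  expect_identical(sim$truth, sim2$truth)
  # all-discriminating boundary
  cfg_all <- sim_config(n_units_per_group = 2, n_variables = 12,
                        n_discriminating = 12, seed = 9)
  sim_all <- simulate_dataset(cfg_all)
  expect_true(all(sim_all$truth$class %in% letters[1:6]))
  # inconsistent mix is a config error
  expect_error(sim_config(n_variables = 100, n_discriminating = 10,
                          class_mix = c(a = 0.5, b = 0, c = 0, d = 0, e = 0,
                                        f = 0, g = 0.25, h = 0.25)),
               "config error")
})

test_that("discriminating classes differ between groups at interior times", {
  cfg <- sim_config(n_units_per_group = 2, n_variables = 80,
                    n_discriminating = 30, seed = 10)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  interior <- cfg$times[2:3]
  for (i in seq_len(nrow(tr))) {
    mi <- mean_curve(tr$c[i], tr$a_int[i], tr$alpha_int[i], tr$beta_int[i],
                     interior)
    mc <- mean_curve(tr$c[i], tr$a_ctrl[i], tr$alpha_ctrl[i], tr$beta_ctrl[i],
                     interior)
    if (tr$discriminating[i]) {
      expect_gt(max(abs(mi - mc)), 1e-8)
    } else {
      expect_equal(mi, mc, tolerance = 1e-12)
    }
  }
})

test_that("train/test pairs share truth but not subjects", {
  cfg <- sim_config(n_units_per_group = 3, n_variables = 40,
                    n_discriminating = 6, seed = 11)
  pair <- simulate_train_test(cfg)
  expect_equal(dim(pair$train$cube$X3), c(6, 40, 4))
  expect_equal(dim(pair$test$cube$X3), c(6, 40, 4))
  expect_length(intersect(pair$train$cube$unit_ids, pair$test$cube$unit_ids), 0)
  expect_equal(sum(pair$truth$discriminating), 6)
})
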