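# Benchmark harness: simulate paired train/test datasets, run each of the
# five models through variable selection on the training set and predictive
# evaluation on the test set, and aggregate the per-repeat metrics.

# Fit one model on full training data and evaluate Q2 / group-classification
# AUC on an independent test set. The classification score is the predicted
# response: per sample for bilinear models, per unit (tri-PLS1 prediction, or
# the unit mean of the predicted two-way response) for trilinear models.
eval_predictive <- function(train, test, spec, design, A) {
  if (spec$x_shape == "bilinear") {
    tr <- if (inherits(train, "long_table")) train else from_cube(train)
    te <- if (inherits(test, "long_table")) test else from_cube(test)
    sc <- autoscale_tolerant(tr$X)
    y <- make_dummy_y(tr, spec, design)
    fit <- fit_pls(sc$X, y, A)
    Xte <- (te$X - rep(sc$means, each = nrow(te$X))) /
      rep(sc$sds, each = nrow(te$X))
    yte <- make_dummy_y(te, spec, design)
    yhat <- predict(fit, Xte)
    list(q2 = q2_score(yte, yhat),
         auc = roc_auc(yhat, te$samples$group))
  } else {
    ctr <- if (inherits(train, "data_cube")) train else to_cube(train)
    cte <- if (inherits(test, "data_cube")) test else to_cube(test)
    pp <- preprocess_cube(ctr)
    cte_p <- apply_cube_preprocess(pp$center, pp$slab, cte)
    Y <- make_dummy_y(ctr, spec, design)
    Yte <- make_dummy_y(cte, spec, design)
    if (spec$y_variant == "trilinear_group") {
      fit <- fit_npls1(pp$cube, Y, A)
      yhat <- predict(fit, cte_p)
      list(q2 = q2_score(Yte, yhat), auc = roc_auc(yhat, cte$group))
    } else {
      fit <- fit_npls2(pp$cube, Y, A)
      Yhat <- predict(fit, cte_p)
      list(q2 = q2_score(Yte, Yhat),
           auc = roc_auc(rowMeans(Yhat), cte$group))
    }
  }
}

#' Benchmark the five PLS models on simulated data
#'
#' For each repeat, a training and an independent test dataset are simulated
#' from `config`. Each requested model is taken through the two-stage
#' evaluation: (1) balanced-bootstrap VIP selection on the training set,
#' scored against the simulation truth (confusion counts,
#' recall/precision/F1, AUVSC); (2) predictive ability (Q2 and group
#' classification AUC, using all variables) on the test set. For models with
#' `n_latent = "auto"` the number of latent variables is determined once, by
#' unit-level cross-validation on the first repeat's training set, and reused
#' for all repeats.
#'
#' @param config a [sim_config()].
#' @param models model ids (subset of 1:5) or a list of [model_spec()]s.
#' @param n_repeats number of simulation repeats (default 10).
#' @param B bootstrap sets per selection (default 200).
#' @param seed integer master seed; all simulation, fold and bootstrap
#'   randomness derives from it.
#' @param design a [response_design()].
#' @param A_max ceiling for the latent-variable search (default 7).
#' @param rule selection rule passed to [bootstrap_vip()].
#' @return Object of class `benchmark_result`: list with `per_repeat` (one
#'   row per model x repeat: `n_latent`, `n_selected`, `TP`, `FP`, `FN`,
#'   `recall`, `precision`, `f1`, `auvsc`, `q2`, `auc`) and `summary`
#'   (mean and sd per model).
#' @export
run_benchmark <- function(config, models = 1:5, n_repeats = 10L, B = 200L,
                          seed = NULL, design = response_design(),
                          A_max = 7L, rule = "vip") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(models)) models <- lapply(models, model_spec)
  stopifnot(all(vapply(models, inherits, logical(1L), "model_spec")))
  seeds <- matrix(derive_seeds(seed, 2L * n_repeats + 1L)[-1L], ncol = 2L)
  A_of <- rep(NA_integer_, length(models))

  rows <- vector("list", length(models) * n_repeats)
  k <- 0L
  for (r in seq_len(n_repeats)) {
    cfg_r <- config; cfg_r$seed <- seeds[r, 1L]
    sim <- simulate_train_test(cfg_r)
    train <- sim$train; test <- sim$test
    train$truth <- sim$truth
    boot_seeds <- derive_seeds(seeds[r, 2L], length(models))
    for (m in seq_along(models)) {
      spec <- models[[m]]
      if (is.na(A_of[m])) {
        A_of[m] <- if (identical(spec$n_latent, "auto")) {
          rmsecv <- cross_validate(train$cube, spec, design, A_max = A_max,
                                   seed = boot_seeds[m])
          choose_n_latent(rmsecv)
        } else as.integer(spec$n_latent)
      }
      data_tr <- if (spec$x_shape == "bilinear") train$table else train$cube
      stats <- bootstrap_vip(data_tr, spec, design, A = A_of[m], B = B,
                             seed = boot_seeds[m], rule = rule)
      sel <- if (rule == "vip") select_variables(stats) else
        select_by_loading_weight(stats)
      conf <- confusion(sel, train$truth)
      prf <- suppressWarnings(prf_scores(conf))
      roc <- vs_roc(stats, train$truth)
      pred <- eval_predictive(train$cube, test$cube, spec, design, A_of[m])
      k <- k + 1L
      rows[[k]] <- data.frame(model = spec$model_id, repeat_id = r,
                              n_latent = A_of[m],
                              n_selected = length(sel),
                              TP = conf$TP, FP = conf$FP, FN = conf$FN,
                              recall = prf[["recall"]],
                              precision = prf[["precision"]],
                              f1 = prf[["f1"]],
                              auvsc = roc$auvsc,
                              q2 = pred$q2, auc = pred$auc)
    }
  }
  per_repeat <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(per_repeat[, -(1:2)],
                               by = list(model = per_repeat$model), mean)
  agg_sd <- stats::aggregate(per_repeat[, -(1:2)],
                             by = list(model = per_repeat$model), stats::sd)
  structure(list(per_repeat = per_repeat,
                 summary = list(mean = agg_mean, sd = agg_sd),
                 n_repeats = n_repeats, B = B),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark over %d repeats (B = %d):\n", x$n_repeats, x$B))
  m <- x$summary$mean; s <- x$summary$sd
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  model %d: #LV %d  Q2 %.2f (%.2f)  AUC %.2f (%.2f)  #sel %.1f (%.1f)  #TP %.1f (%.1f)  recall %.2f  precision %.2f  F1 %.2f  AUVSC %.3f\n",
                m$model[i], m$n_latent[i], m$q2[i], s$q2[i], m$auc[i], s$auc[i],
                m$n_selected[i], s$n_selected[i], m$TP[i], s$TP[i],
                m$recall[i], m$precision[i], m$f1[i], m$auvsc[i]))
  }
  invisible(x)
}
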