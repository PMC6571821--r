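#' Variable-selection confusion counts
#'
#' Cross-tabulates a selected variable set against the known discriminating /
#' non-discriminating status of each variable: selected discriminating
#' variables are true positives, selected non-discriminating ones false
#' positives, and so on.
#'
#' @param selected integer vector of selected variable indices.
#' @param truth a `sim_truth` data.frame (from [simulate_dataset()]) or a
#'   logical vector flagging the truly discriminating variables.
#' @return List of class `confusion` with integer fields `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion <- function(selected, truth) {
  disc <- if (inherits(truth, "data.frame")) truth$discriminating else as.logical(truth)
  J <- length(disc)
  selected <- as.integer(selected)
  if (length(selected) && (min(selected) < 1L || max(selected) > J))
    stop("index error: selected indices outside 1..J", call. = FALSE)
  sel <- rep(FALSE, J); sel[selected] <- TRUE
  structure(list(TP = sum(sel & disc), FP = sum(sel & !disc),
                 FN = sum(!sel & disc), TN = sum(!sel & !disc)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Recall, precision and F-score from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F_beta = (beta^2 + 1) precision recall / (beta^2 precision + recall)`.
#' With the default `beta = 1` the F-score is the harmonic mean of precision
#' and recall. Undefined ratios (empty selection or no discriminating
#' variables) are returned as `NA` with a warning.
#'
#' @param conf a [confusion()] object.
#' @param beta recall weight in the F-score (default 1).
#' @return Named numeric vector `c(recall, precision, f1)`.
#' @export
prf_scores <- function(conf, beta = 1) {
  stopifnot(inherits(conf, "confusion"))
  recall <- if (conf$TP + conf$FN == 0L) {
    warning("recall undefined: no discriminating variables"); NA_real_
  } else conf$TP / (conf$TP + conf$FN)
  precision <- if (conf$TP + conf$FP == 0L) {
    warning("precision undefined: empty selection"); NA_real_
  } else conf$TP / (conf$TP + conf$FP)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
  else if (precision + recall == 0) 0
  else (beta^2 + 1) * precision * recall / (beta^2 * precision + recall)
  c(recall = recall, precision = precision, f1 = f1)
}

#' Variable-selection ROC curve and its area (AUVSC)
#'
#' Sweeps a threshold over the per-variable ranking statistic
#' `VIP* - sigma_VIP` (the left-hand side of the selection rule) from high to
#' low; at each threshold the true positive rate is the fraction of
#' discriminating variables selected and the false positive rate the fraction
#' of non-discriminating variables selected. The area under this curve
#' (trapezoid rule; equal to the Mann-Whitney statistic of the ranking scores
#' between the two truth classes) summarizes ranking quality independent of
#' the selection threshold.
#'
#' @param stats a `vip_stats` data.frame from [bootstrap_vip()].
#' @param truth a `sim_truth` data.frame or logical discriminating flags.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auvsc`.
#' @export
vs_roc <- function(stats, truth) {
  stopifnot(inherits(stats, "vip_stats"))
  disc <- if (inherits(truth, "data.frame")) truth$discriminating else as.logical(truth)
  if (length(disc) != nrow(stats))
    stop("truth flags must match the number of variables", call. = FALSE)
  if (all(disc) || !any(disc))
    stop("undefined error: need both discriminating and non-discriminating variables",
         call. = FALSE)
  score <- stats$vip_mean - stats$vip_sd
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(disc[ord]); fp <- cumsum(!disc[ord])
  # collapse tied scores: keep the last point of each tied block
  keep <- c(diff(score[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(disc))
  fpr <- c(0, fp[keep] / sum(!disc))
  auvsc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(curve = data.frame(threshold = c(Inf, score[ord][keep]),
                          fpr = fpr, tpr = tpr),
       auvsc = auvsc)
}

#' Permutation test of model validity
#'
#' Permutes the group labels at the unit level and compares the
#' cross-validated predictive ability (Q2 from [cross_validate()], at the
#' chosen number of latent variables) of the observed labelling against the
#' permutation null. The p-value uses the add-one estimator
#' `p = (1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param data a [long_table()] or `data_cube`.
#' @param spec a [model_spec()].
#' @param design a [response_design()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param A_max ceiling for the latent-variable search when
#'   `spec$n_latent = "auto"`.
#' @param n_folds passed to [cross_validate()].
#' @return List of class `perm_test` with `p_value`, `observed` (Q2),
#'   `permuted` (numeric vector), `n_latent`.
#' @export
permutation_test <- function(data, spec, design = response_design(),
                             n_perm = 1000L, seed = NULL, A_max = 7L,
                             n_folds = NULL) {
  if (n_perm < 1L) stop("config error: n_perm must be >= 1", call. = FALSE)
  if (spec$x_shape == "trilinear" && inherits(data, "long_table"))
    data <- to_cube(data)
  seeds <- derive_seeds(seed, 2L)
  cv_stat <- function(d, A = NULL) {
    rmsecv <- cross_validate(d, spec, design, A_max = A_max,
                             n_folds = n_folds, seed = seeds[1L])
    if (is.null(A)) A <- choose_n_latent(rmsecv)
    list(q2 = attr(rmsecv, "q2cv")[A], A = A)
  }
  if (identical(spec$n_latent, "auto")) {
    obs <- cv_stat(data)
  } else {
    obs <- cv_stat(data, A = spec$n_latent)
  }
  permuted <- numeric(n_perm)
  with_seed(seeds[2L], {
    for (i in seq_len(n_perm)) {
      d <- data
      if (inherits(d, "data_cube")) {
        d$group <- sample(d$group)
      } else {
        units <- unique(d$samples$unit)
        g <- d$samples$group[match(units, d$samples$unit)]
        gp <- sample(g)
        d$samples$group <- gp[match(d$samples$unit, units)]
      }
      permuted[i] <- cv_stat(d, A = obs$A)$q2
    }
  })
  structure(list(p_value = (1 + sum(permuted >= obs$q2)) / (n_perm + 1),
                 observed = obs$q2, permuted = permuted, n_latent = obs$A),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: observed Q2 = %.3f, p = %.4g (%d permutations, %d LV)\n",
              x$observed, x$p_value, length(x$permuted), x$n_latent))
  invisible(x)
}

#' Flag discriminating variables by per-time-point t-tests
#'
#' Applies a two-sample Welch t-test between groups at each time point and
#' flags a variable when at least one time point is significant at the nominal
#' level `alpha`. Used to label "truly" discriminating variables in real
#' datasets where the ground truth is unknown.
#'
#' @param tbl a [long_table()] with both groups present.
#' @param alpha nominal significance level (default 0.05).
#' @return Logical vector of length J.
#' @export
ttest_flag <- function(tbl, alpha = 0.05) {
  stopifnot(inherits(tbl, "long_table"))
  s <- tbl$samples
  times <- sort(unique(s$time))
  minp <- rep(Inf, ncol(tbl$X))
  for (tt in times) {
    r1 <- s$time == tt & as.integer(s$group) == 1L
    r2 <- s$time == tt & as.integer(s$group) == 2L
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 2L || n2 < 2L)
      stop(sprintf("design error: fewer than 2 samples in a group at time %g", tt),
           call. = FALSE)
    X1 <- tbl$X[r1, , drop = FALSE]; X2 <- tbl$X[r2, , drop = FALSE]
    m1 <- colMeans(X1); m2 <- colMeans(X2)
    v1 <- colSums(sweep(X1, 2L, m1, "-")^2) / (n1 - 1L)
    v2 <- colSums(sweep(X2, 2L, m2, "-")^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[se2 == 0] <- 1
    minp <- pmin(minp, p)
  }
  minp < alpha
}
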