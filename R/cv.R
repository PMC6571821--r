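#' Unit-level cross-validation of a PLS model
#'
#' A single cross-validation scheme over experimental units: folds partition
#' the units (all time points of a unit stay together, so repeated measures
#' never leak between training and held-out sets). Preprocessing (autoscaling
#' for bilinear models, centring + slab scaling for trilinear models) is refit
#' inside each fold and applied to the held-out data.
#'
#' @param data a [long_table()] (any model) or `data_cube` (models 4-5).
#' @param spec a [model_spec()].
#' @param design a [response_design()].
#' @param A_max largest number of latent variables to evaluate (capped at what
#'   the training folds support).
#' @param n_folds number of folds; default: leave-one-unit-out when there are
#'   at most 10 units, otherwise 7 folds.
#' @param seed integer seed for the fold assignment.
#' @return Numeric vector `rmsecv` of length `<= A_max`:
#'   `rmsecv[a] = sqrt(sum((y - yhat_cv)^2) / n)` with a components.
#'   Attributes: `folds` (unit fold assignment), `press` (per component),
#'   `tss` (total sum of squares about the grand response mean), `q2cv`
#'   (cross-validated Q2 per component).
#' @seealso [choose_n_latent()]
#' @export
cross_validate <- function(data, spec, design = response_design(), A_max = 7L,
                           n_folds = NULL, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$x_shape == "trilinear" && inherits(data, "long_table"))
    data <- to_cube(data)
  if (spec$x_shape == "bilinear" && inherits(data, "data_cube"))
    data <- from_cube(data)
  units <- if (inherits(data, "data_cube")) data$unit_ids else
    sort(unique(data$samples$unit))
  n_units <- length(units)
  if (is.null(n_folds)) n_folds <- if (n_units <= 10L) n_units else 7L
  if (n_folds > n_units)
    stop("fold error: more folds than experimental units", call. = FALSE)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(n_folds), n_units)))
  names(fold_of) <- units

  Y <- make_dummy_y(data, spec, design)
  ymat <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1L)

  if (spec$x_shape == "bilinear") {
    unit_of_row <- data$samples$unit
    n_train_min <- min(vapply(seq_len(n_folds), function(k)
      sum(unit_of_row %in% units[fold_of != k]), integer(1L)))
    A_cap <- min(A_max, n_train_min - 1L, ncol(data$X))
  } else {
    d <- dim(data$X3)
    n_train_min <- min(vapply(seq_len(n_folds), function(k)
      sum(fold_of != k), integer(1L)))
    A_cap <- min(A_max, n_train_min - 1L, d[2L] * d[3L])
  }
  if (A_cap < 1L) stop("fold error: training folds too small to fit a model",
                       call. = FALSE)

  press <- numeric(A_cap)
  n_obs <- 0L
  for (k in seq_len(n_folds)) {
    test_units <- units[fold_of == k]
    if (spec$x_shape == "bilinear") {
      te <- unit_of_row %in% test_units
      sc <- autoscale_tolerant(data$X[!te, , drop = FALSE])
      Xte <- (data$X[te, , drop = FALSE] -
                rep(sc$means, each = sum(te))) / rep(sc$sds, each = sum(te))
      fit <- fit_pls(sc$X, Y[!te], A_cap)
      for (a in seq_len(A_cap)) {
        yhat <- drop(Xte %*% fit$coefficients[, a]) + fit$y_mean
        press[a] <- press[a] + sum((Y[te] - yhat)^2)
      }
      n_obs <- n_obs + sum(te)
    } else {
      tr <- !(units %in% test_units)
      Utr <- unfold_mode1(data$X3[tr, , , drop = FALSE])
      pp <- preprocess_unfolded(Utr, d[2L], d[3L])
      Ute <- unfold_mode1(data$X3[!tr, , , drop = FALSE])
      Ute <- (Ute - rep(pp$means, each = nrow(Ute))) /
        rep(rep(pp$rms, d[3L]), each = nrow(Ute))
      if (spec$y_variant == "trilinear_group") {
        fit <- npls1_core(pp$U, d[2L], d[3L], Y[tr], A_cap)
        for (a in seq_len(A_cap)) {
          yhat <- npls_project(fit, Ute, a, d[2L]) %*% fit$b[[a]] + fit$y_mean
          press[a] <- press[a] + sum((Y[!tr] - drop(yhat))^2)
        }
        n_obs <- n_obs + sum(!tr)
      } else {
        cube_tr <- subset_cube(data, which(tr))
        cube_tr$X3 <- fold_mode1(pp$U, d[2L], d[3L])
        fit <- fit_npls2(cube_tr, ymat[tr, , drop = FALSE], A_cap)
        for (a in seq_len(A_cap)) {
          yhat <- npls_project(fit, Ute, a, d[2L]) %*% fit$b[[a]] +
            rep(fit$y_mean, each = sum(!tr))
          press[a] <- press[a] + sum((ymat[!tr, , drop = FALSE] - yhat)^2)
        }
        n_obs <- n_obs + sum(!tr) * ncol(ymat)
      }
    }
  }
  tss <- sum(sweep(ymat, 2L, colMeans(ymat), "-")^2)
  rmsecv <- sqrt(press / n_obs)
  attr(rmsecv, "folds") <- fold_of
  attr(rmsecv, "press") <- press
  attr(rmsecv, "tss") <- tss
  attr(rmsecv, "q2cv") <- 1 - press / tss
  rmsecv
}

# Project an unfolded (already preprocessed) cube matrix through the first
# `ncomp` components of a fitted trilinear model; returns the score matrix.
npls_project <- function(fit, U, ncomp, J) {
  Tnew <- matrix(0, nrow(U), ncomp)
  for (a in seq_len(ncomp)) {
    rvec <- as.numeric(outer(fit$WJ[, a], fit$WK[, a]))
    t <- drop(U %*% rvec)
    Tnew[, a] <- t
    U <- U - tcrossprod(t, rvec)
  }
  Tnew
}

# Subset a data_cube to a set of unit indices (duplicates allowed, for
# bootstrap resampling).
subset_cube <- function(cube, idx) {
  out <- cube
  out$X3 <- cube$X3[idx, , , drop = FALSE]
  out$unit_ids <- make.unique(cube$unit_ids[idx])
  out$group <- cube$group[idx]
  out$subjects <- cube$subjects[idx]
  out
}

#' Choose the number of latent variables from an RMSECV curve
#'
#' The number of latent variables is the smallest a at which the relative
#' decrease in RMSECV from a to a + 1 falls below `rel_threshold` (default 2
#' percent); if the curve keeps improving by more than the threshold up to its
#' end, the full length is returned. A zero or negative decrease triggers the
#' rule immediately, and ties break toward the smaller a.
#'
#' @param rmsecv positive numeric vector of cross-validated RMSE by number of
#'   components (from [cross_validate()]).
#' @param rel_threshold relative-decrease threshold (default 0.02).
#' @return Integer number of latent variables.
#' @export
choose_n_latent <- function(rmsecv, rel_threshold = 0.02) {
  rmsecv <- as.numeric(rmsecv)
  if (length(rmsecv) == 0L) stop("input error: empty RMSECV curve", call. = FALSE)
  if (any(!is.finite(rmsecv)) || any(rmsecv <= 0))
    stop("input error: RMSECV values must be positive", call. = FALSE)
  if (length(rmsecv) == 1L) return(1L)
  for (a in seq_len(length(rmsecv) - 1L)) {
    if ((rmsecv[a] - rmsecv[a + 1L]) / rmsecv[a] < rel_threshold) return(a)
  }
  length(rmsecv)
}

#' Predictive variance explained (Q2)
#'
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Applied to held-out
#' predictions this is the cross-validated or test-set predictive ability; 1
#' means perfect prediction, 0 means no better than the response mean.
#'
#' @param y_true observed responses (vector or matrix).
#' @param y_pred predicted responses, same shape.
#' @return Numeric Q2.
#' @export
q2_score <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!identical(dim(y_true), dim(y_pred)))
    stop("dimension error: y_true and y_pred must have the same shape", call. = FALSE)
  tss <- sum(sweep(y_true, 2L, colMeans(y_true), "-")^2)
  if (tss <= 0)
    stop("undefined error: constant y_true gives an undefined Q2", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / tss
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a randomly
#' chosen positive sample outscores a randomly chosen negative one, with ties
#' counted one half.
#'
#' @param scores numeric classification scores (larger = more positive-like).
#' @param labels binary labels: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) == 2L
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("undefined error: AUC needs both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}
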