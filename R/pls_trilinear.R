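#' @name trilinear_pls
#' @title Trilinear (N-PLS) regression on data cubes
#'
#' @description Tri-PLS decomposes a units x variables x time array into
#' rank-one weight structures, one per latent variable: each component has a
#' unit-norm variable-mode weight `wJ` (length J), a unit-norm time-mode
#' weight `wK` (length T), and a score per unit `t_s = wJ' X_s wK` where `X_s`
#' is the J x T slice for unit s. Component weights are chosen to maximize the
#' covariance between the scores and the (residual) response; the response is
#' regressed on all extracted scores and both the array and the response are
#' deflated after each component. Compared to unfolded bilinear PLS this keeps
#' the variable and time modes separate, giving fewer parameters and more
#' interpretable weights.
NULL

# Dominant singular pair of Z (J x T) with deterministic sign: the
# largest-magnitude entry of the variable-mode vector is made positive
# (jointly flipping both vectors, which leaves scores unchanged).
dominant_pair <- function(Z) {
  sv <- svd(Z, nu = 1L, nv = 1L)
  if (length(sv$d) > 1L && sv$d[1L] > 0 &&
      (sv$d[1L] - sv$d[2L]) / sv$d[1L] < 1e-12)
    stop("tie error: top singular values of the covariance matrix coincide; weight direction undefined",
         call. = FALSE)
  wj <- sv$u[, 1L]; wk <- sv$v[, 1L]
  if (wj[which.max(abs(wj))] < 0) { wj <- -wj; wk <- -wk }
  list(wj = wj, wk = wk, d = sv$d[1L])
}

npls_check_ncomp <- function(ncomp, Sn, J, Tn) {
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(Sn - 1L, J * Tn))
    stop(sprintf("component error: ncomp must be in 1..min(S'-1, J*T) = %d",
                 min(Sn - 1L, J * Tn)), call. = FALSE)
  ncomp
}

# Core tri-PLS1 on an unfolded cube matrix U (S' x J*T). Returns the pieces
# shared by the public constructors.
npls1_core <- function(U, J, Tn, y, ncomp) {
  Sn <- nrow(U)
  y_mean <- mean(y)
  yc <- y - y_mean
  yres <- yc
  WJ <- matrix(0, J, ncomp); WK <- matrix(0, Tn, ncomp)
  Tm <- matrix(0, Sn, ncomp); ssy <- numeric(ncomp)
  bcoef <- vector("list", ncomp)
  for (a in seq_len(ncomp)) {
    z <- crossprod(U, yres)
    if (sqrt(sum(z^2)) < 1e-12)
      stop("degenerate response error: response has no covariance with the cube",
           call. = FALSE)
    pr <- dominant_pair(matrix(z, J, Tn))
    rvec <- as.numeric(outer(pr$wj, pr$wk))  # kronecker(wk, wj) in unfold order
    t <- drop(U %*% rvec)
    WJ[, a] <- pr$wj; WK[, a] <- pr$wk; Tm[, a] <- t
    Ta <- Tm[, seq_len(a), drop = FALSE]
    b <- qr.solve(Ta, yc)
    bcoef[[a]] <- b
    prev <- sum(yres^2)
    yres <- yc - drop(Ta %*% b)
    ssy[a] <- prev - sum(yres^2)
    U <- U - tcrossprod(t, rvec)
  }
  list(WJ = WJ, WK = WK, scores = Tm, b = bcoef, ssy = ssy, y_mean = y_mean,
       fitted = drop(Tm %*% bcoef[[ncomp]]) + y_mean)
}

#' Fit a tri-PLS1 model (vector response)
#'
#' @param cube a `data_cube`, preprocessed over the first mode (see
#'   [preprocess_cube()]).
#' @param y numeric response, one value per unit (e.g. group codes from
#'   [make_dummy_y()] with model 4); centred internally.
#' @param ncomp number of latent variables, at most `min(S' - 1, J, T)`.
#' @return An object of class `tripls_model` (type `"npls1"`) with per
#'   component the variable-mode weights `WJ` (J x A, unit columns), time-mode
#'   weights `WK` (T x A), unit scores, score-regression coefficients, `ssy`
#'   (response sum of squares explained per component, from the sequential
#'   deflation residuals), `y_mean`, `fitted`.
#' @seealso [predict.tripls_model()], [fit_npls2()]
#' @export
fit_npls1 <- function(cube, y, ncomp) {
  stopifnot(inherits(cube, "data_cube"))
  d <- dim(cube$X3)
  ncomp <- npls_check_ncomp(ncomp, d[1L], d[2L], d[3L])
  y <- as.numeric(y)
  if (length(y) != d[1L]) stop("length(y) must equal the number of units", call. = FALSE)
  core <- npls1_core(unfold_mode1(cube$X3), d[2L], d[3L], y, ncomp)
  structure(c(core, list(type = "npls1", ncomp = ncomp, J = d[2L], Tn = d[3L],
                         variable_ids = cube$variable_ids, times = cube$times)),
            class = "tripls_model")
}

#' Fit a tri-PLS2 model (matrix response)
#'
#' Tri-PLS2 handles a multivariate response (here the two-way dummy Y of model
#' 5: units x time). Each component alternates between a response weight `q`
#' and the rank-one cube weights until the score vector converges, then the
#' response is regressed on all scores and both blocks are deflated.
#'
#' @param cube a preprocessed `data_cube`.
#' @param Y numeric matrix, one row per unit; columns are response variables
#'   (centred internally).
#' @param ncomp number of latent variables.
#' @param tol relative convergence tolerance on the score vector (default
#'   1e-10).
#' @param max_iter maximum inner iterations per component (default 500).
#' @return A `tripls_model` of type `"npls2"`; `b` holds, per truncation level
#'   a, the a x M score-regression coefficient matrix.
#' @export
fit_npls2 <- function(cube, Y, ncomp, tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(cube, "data_cube"))
  d <- dim(cube$X3)
  ncomp <- npls_check_ncomp(ncomp, d[1L], d[2L], d[3L])
  Y <- as.matrix(Y)
  if (nrow(Y) != d[1L]) stop("nrow(Y) must equal the number of units", call. = FALSE)
  Sn <- d[1L]; J <- d[2L]; Tn <- d[3L]; M <- ncol(Y)
  U <- unfold_mode1(cube$X3)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_means, "-")
  Yres <- Yc
  WJ <- matrix(0, J, ncomp); WK <- matrix(0, Tn, ncomp); Q <- matrix(0, M, ncomp)
  Tm <- matrix(0, Sn, ncomp); ssy <- numeric(ncomp)
  bcoef <- vector("list", ncomp)
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(Yres^2)) < 1e-12 || sqrt(sum(crossprod(U, Yres)^2)) < 1e-12)
      stop("degenerate response error: response has no covariance with the cube",
           call. = FALSE)
    u <- Yres[, which.max(apply(Yres, 2L, stats::var))]
    t_old <- rep(0, Sn)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      pr <- dominant_pair(matrix(crossprod(U, u), J, Tn))
      rvec <- as.numeric(outer(pr$wj, pr$wk))
      t <- drop(U %*% rvec)
      qw <- drop(crossprod(Yres, t))
      nq <- sqrt(sum(qw^2))
      if (nq < 1e-12)
        stop("degenerate response error: null response weight", call. = FALSE)
      qw <- qw / nq
      u <- drop(Yres %*% qw)
      if (sqrt(sum((t - t_old)^2)) <= tol * max(sqrt(sum(t^2)), 1e-300)) break
      if (iter >= max_iter)
        stop(sprintf("convergence error: tri-PLS2 component %d did not converge in %d iterations (last change %.3e)",
                     a, max_iter, sqrt(sum((t - t_old)^2))), call. = FALSE)
      t_old <- t
    }
    WJ[, a] <- pr$wj; WK[, a] <- pr$wk; Q[, a] <- qw; Tm[, a] <- t
    Ta <- Tm[, seq_len(a), drop = FALSE]
    B <- qr.solve(Ta, Yc)
    if (a == 1L) B <- matrix(B, nrow = 1L)
    bcoef[[a]] <- B
    prev <- sum(Yres^2)
    Yres <- Yc - Ta %*% B
    ssy[a] <- prev - sum(Yres^2)
    U <- U - tcrossprod(t, rvec)
  }
  structure(list(WJ = WJ, WK = WK, y_weights = Q, scores = Tm, b = bcoef,
                 ssy = ssy, y_mean = y_means,
                 fitted = Tm %*% bcoef[[ncomp]] +
                   rep(y_means, each = Sn),
                 type = "npls2", ncomp = ncomp, J = J, Tn = Tn,
                 variable_ids = cube$variable_ids, times = cube$times),
            class = "tripls_model")
}

#' @export
print.tripls_model <- function(x, ...) {
  cat(sprintf("trilinear PLS model (%s): %d variables x %d time points, %d latent variable(s)\n",
              x$type, x$J, x$Tn, x$ncomp))
  invisible(x)
}

#' Predict from a trilinear PLS model
#'
#' New units are projected through the training component sequence: per
#' component the unit score is `wJ' X_s wK` on the deflated slice, then the
#' stored score regression is applied and the training response mean added.
#'
#' @param object a `tripls_model`.
#' @param newdata a `data_cube` (preprocessed with the training states) with
#'   the same variables and time grid as the training cube.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return Numeric vector (tri-PLS1) or matrix (tri-PLS2) of predicted
#'   responses.
#' @export
predict.tripls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  stopifnot(inherits(newdata, "data_cube"))
  d <- dim(newdata$X3)
  if (d[2L] != object$J || d[3L] != object$Tn)
    stop("shape error: newdata cube does not match the training dimensions",
         call. = FALSE)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("component error: ncomp out of range", call. = FALSE)
  U <- unfold_mode1(newdata$X3)
  Tnew <- matrix(0, d[1L], ncomp)
  for (a in seq_len(ncomp)) {
    rvec <- as.numeric(outer(object$WJ[, a], object$WK[, a]))
    t <- drop(U %*% rvec)
    Tnew[, a] <- t
    U <- U - tcrossprod(t, rvec)
  }
  if (object$type == "npls1") {
    drop(Tnew %*% object$b[[ncomp]]) + object$y_mean
  } else {
    Tnew %*% object$b[[ncomp]] + rep(object$y_mean, each = d[1L])
  }
}
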