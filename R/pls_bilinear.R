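#' Fit a bilinear PLS1 regression model
#'
#' Standard NIPALS PLS1: latent variables are extracted to maximize the
#' covariance between the predictor matrix and a single response vector. The
#' first component weight is the normalized covariance direction
#' `w1 = X'y / ||X'y||`; after each component the predictor matrix is deflated
#' by the extracted score/loading outer product (X-only deflation). The
#' response is centred internally; the predictors are expected to be
#' preprocessed already (see [autoscale_bilinear()]).
#'
#' @param X numeric matrix (n x J), preprocessed (centred/scaled).
#' @param y numeric response vector of length n (a dummy response from
#'   [make_dummy_y()], or any numeric response).
#' @param ncomp number of latent variables A, `A <= min(n - 1, J)`.
#' @return An object of class `bipls` with components: `weights` W (J x A,
#'   unit-norm columns), `scores` T (n x A, mutually orthogonal), `loadings` P,
#'   `y_loadings` q, `coefficients` (J x A; column a gives the regression
#'   vector using a components), `ssy` (response sum of squares explained per
#'   component), `y_mean`, `fitted`, `ncomp`.
#' @seealso [predict.bipls()], [vip()]
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); J <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, J))
    stop(sprintf("component error: ncomp must be in 1..min(n-1, J) = %d",
                 min(n - 1L, J)), call. = FALSE)
  y_mean <- mean(y)
  yc <- y - y_mean
  W <- matrix(0, J, ncomp); P <- matrix(0, J, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp); ssy <- numeric(ncomp)
  Xres <- X
  for (a in seq_len(ncomp)) {
    wv <- crossprod(Xres, yc)        # X-only deflation: X_res' yc = X_res' y_res
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12)
      stop("degenerate response error: response has no covariance with X",
           call. = FALSE)
    w <- wv / nw
    t <- drop(Xres %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24)
      stop("component error: null score vector extracted", call. = FALSE)
    p <- drop(crossprod(Xres, t)) / tt
    q <- sum(yc * t) / tt
    Xres <- Xres - tcrossprod(t, p)
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; qv[a] <- q
    ssy[a] <- q^2 * tt
  }
  # regression vector for each truncation level a: B_a = W_a (P_a' W_a)^{-1} q_a
  coefs <- matrix(0, J, ncomp)
  for (a in seq_len(ncomp)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- crossprod(Pa, Wa)           # a x a, upper triangular in exact arithmetic
    coefs[, a] <- Wa %*% solve(R, qv[seq_len(a)])
  }
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = qv,
                 coefficients = coefs, ssy = ssy, y_mean = y_mean,
                 fitted = drop(X %*% coefs[, ncomp]) + y_mean,
                 ncomp = ncomp),
            class = "bipls")
}

#' @export
print.bipls <- function(x, ...) {
  cat(sprintf("bilinear PLS1 model: %d variables, %d latent variable(s)\n",
              nrow(x$weights), x$ncomp))
  invisible(x)
}

#' Predict from a bilinear PLS model
#'
#' @param object a `bipls` model.
#' @param newdata matrix with the same variables (preprocessed with the
#'   training scaling state).
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return Numeric vector of predicted responses
#'   (`newdata %*% B + training y mean`).
#' @export
predict.bipls <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefficients))
    stop("dimension error: newdata has wrong number of columns", call. = FALSE)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("component error: ncomp out of range", call. = FALSE)
  drop(newdata %*% object$coefficients[, ncomp]) + object$y_mean
}
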