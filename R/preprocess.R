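#' Centring and scaling for bilinear and trilinear data
#'
#' Prior to PLS modelling the data are centred across the first mode (samples
#' for a two-way table, units for a three-way cube). Two-way data are
#' additionally autoscaled (each column to unit variance). Three-way data use
#' single-slab scaling: each variable's S' x T slice is divided by its
#' root-mean-square so the whole slab has unit RMS, which scales the variable
#' without distorting the relative pattern across time.
#'
#' @name preprocess
NULL

new_scaling_state <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "scaling_state")
}

#' @export
print.scaling_state <- function(x, ...) {
  cat(sprintf("scaling_state: %s\n", x$type))
  invisible(x)
}

#' Autoscale a two-way matrix
#'
#' Centres each column to mean zero and scales it to unit sample variance
#' (denominator n - 1).
#'
#' @param X numeric matrix (samples x variables), at least two rows.
#' @return List with `X` (scaled matrix) and `state` (a `scaling_state`
#'   storing column means and sds, applicable to new data with
#'   [apply_scaling()]).
#' @export
autoscale_bilinear <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  zv <- which(sds <= 0 | !is.finite(sds))
  if (length(zv))
    stop(sprintf("degenerate variable error: zero-variance column(s): %s",
                 paste(utils::head(colnames(X)[zv] %||% zv, 10L), collapse = ", ")),
         call. = FALSE)
  list(X = sweep(Xc, 2L, sds, "/"),
       state = new_scaling_state("autoscale", means = mu, sds = sds))
}

# Tolerant internal variant used inside CV/bootstrap loops: columns that are
# constant in a resampled subset carry no information and are mapped to zero
# rather than raising an error. Returns the count of such columns.
autoscale_tolerant <- function(X) {
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = nrow(X))
  sds <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  zv <- sds <= 0 | !is.finite(sds)
  sds[zv] <- 1
  list(X = Xc / rep(sds, each = nrow(X)),
       means = mu, sds = sds, n_constant = sum(zv))
}

#' Apply a stored scaling state to new data
#'
#' @param state a `scaling_state` from [autoscale_bilinear()].
#' @param X new matrix with the same variables as the training data.
#' @return Scaled matrix.
#' @export
apply_scaling <- function(state, X) {
  stopifnot(inherits(state, "scaling_state"), state$type == "autoscale")
  X <- as.matrix(X)
  if (ncol(X) != length(state$means))
    stop("dimension error: column count does not match scaling state", call. = FALSE)
  sweep(sweep(X, 2L, state$means, "-"), 2L, state$sds, "/")
}

#' Centre a data cube across the first (unit) mode
#'
#' Subtracts from every fibre `X3[, j, t]` its mean over units, so each
#' variable/time combination has mean zero across units.
#'
#' @param cube a `data_cube` with at least two units.
#' @return List with `cube` (centred) and `state` (means, a J x T matrix).
#' @export
center_cube_mode1 <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  d <- dim(cube$X3)
  if (d[1L] < 2L) stop("centring needs at least 2 units", call. = FALSE)
  mu <- apply(cube$X3, c(2L, 3L), mean)
  X3 <- sweep(cube$X3, c(2L, 3L), mu, "-")
  out <- cube; out$X3 <- X3
  list(cube = out, state = new_scaling_state("center_cube", means = mu))
}

#' Single-slab scaling of a data cube
#'
#' Divides each variable slab `X3[, j, ]` by its root-mean-square
#' `RMS_j = sqrt(sum_s sum_t x_sjt^2 / (S' T))`, giving every slab unit RMS.
#'
#' @param cube a `data_cube`; apply after [center_cube_mode1()].
#' @return List with `cube` (scaled) and `state` (slab RMS values).
#' @export
slab_scale <- function(cube) {
  stopifnot(inherits(cube, "data_cube"))
  d <- dim(cube$X3)
  rms <- sqrt(apply(cube$X3^2, 2L, sum) / (d[1L] * d[3L]))
  zv <- which(rms <= 0 | !is.finite(rms))
  if (length(zv))
    stop(sprintf("degenerate variable error: all-zero slab(s): %s",
                 paste(utils::head(cube$variable_ids[zv], 10L), collapse = ", ")),
         call. = FALSE)
  out <- cube
  out$X3 <- sweep(cube$X3, 2L, rms, "/")
  list(cube = out, state = new_scaling_state("slab_scale", rms = rms))
}

#' Standard trilinear preprocessing: centre, then slab-scale
#'
#' @param cube a `data_cube`.
#' @return List with `cube` and the two states (`center`, `slab`).
#' @export
preprocess_cube <- function(cube) {
  ctr <- center_cube_mode1(cube)
  sc <- slab_scale(ctr$cube)
  list(cube = sc$cube, center = ctr$state, slab = sc$state)
}

#' Apply stored cube preprocessing to new data
#'
#' @param center,slab scaling states from [preprocess_cube()].
#' @param cube new `data_cube` with the same variables and time grid.
#' @return Preprocessed `data_cube`.
#' @export
apply_cube_preprocess <- function(center, slab, cube) {
  stopifnot(inherits(cube, "data_cube"),
            center$type == "center_cube", slab$type == "slab_scale")
  d <- dim(cube$X3)
  if (d[2L] != nrow(center$means) || d[3L] != ncol(center$means))
    stop("dimension error: cube does not match preprocessing state", call. = FALSE)
  out <- cube
  out$X3 <- sweep(sweep(cube$X3, c(2L, 3L), center$means, "-"), 2L, slab$rms, "/")
  out
}

# Preprocess an already-unfolded cube matrix (S' x J*T): centre columns, then
# slab-scale. Fast path for bootstrap/CV loops. Zero slabs are left unscaled.
preprocess_unfolded <- function(U, J, Tn) {
  mu <- colMeans(U)
  Uc <- U - rep(mu, each = nrow(U))
  rms <- sqrt(rowSums(matrix(colSums(Uc^2), J, Tn)) / (nrow(U) * Tn))
  rms[rms <= 0 | !is.finite(rms)] <- 1
  list(U = Uc / rep(rep(rms, Tn), each = nrow(U)), means = mu, rms = rms)
}

#' Serialize a scaling state to JSON
#'
#' @param state a `scaling_state`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
scaling_state_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "scaling_state"))
  js <- jsonlite::toJSON(unclass(state), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a scaling state from JSON
#'
#' @param path file written by [scaling_state_json()].
#' @return A `scaling_state`.
#' @export
read_scaling_state <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (obj$type == "center_cube") obj$means <- as.matrix(obj$means)
  structure(obj, class = "scaling_state")
}
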