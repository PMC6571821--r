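#' Variable importance in projection (VIP)
#'
#' Per-variable summary of weight contributions across latent variables,
#' weighted by the response sum of squares each component explains:
#' `VIP_j = sqrt( J * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight vectors. The normalization makes the squared VIPs average one
#' (`sum_j VIP_j^2 = J`), so 1 is the natural "average importance" reference.
#' For trilinear models the variable-mode weights `wJ` play the role of `w`.
#'
#' @param model a fitted [fit_pls()] (`bipls`) or [fit_npls1()] /
#'   [fit_npls2()] (`tripls_model`) model.
#' @return Numeric vector of length J.
#' @export
vip <- function(model) UseMethod("vip")

vip_from_weights <- function(W, ssy) {
  tot <- sum(ssy)
  if (!is.finite(tot) || tot <= 0)
    stop("degenerate error: model explains no response variance", call. = FALSE)
  drop(sqrt(nrow(W) * (W^2 %*% ssy) / tot))
}

#' @export
vip.bipls <- function(model) vip_from_weights(model$weights, model$ssy)

#' @export
vip.tripls_model <- function(model) vip_from_weights(model$WJ, model$ssy)

# First-component loading-weight statistic, scaled by sqrt(J) so its squared
# values average 1 and the same threshold-1 selection rule applies.
loading_weight_stat <- function(model, component = 1L) {
  W <- if (inherits(model, "bipls")) model$weights else model$WJ
  if (component > ncol(W))
    stop("component error: component exceeds the number fitted", call. = FALSE)
  sqrt(nrow(W)) * abs(W[, component])
}

#' Balanced bootstrap index sets
#'
#' Concatenates B copies of `1..n`, applies one seeded uniform permutation and
#' splits the result into B blocks of length n. Across all B sets every unit
#' index appears exactly B times, which reduces the Monte-Carlo variance of
#' bootstrap means compared to independent resampling.
#'
#' @param n number of experimental units.
#' @param B number of bootstrap sets.
#' @param seed integer seed.
#' @return List of B integer vectors of length n.
#' @export
balanced_bootstrap_indices <- function(n, B, seed = NULL) {
  if (n < 2L) stop("need at least 2 units", call. = FALSE)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  perm <- with_seed(seed, sample(rep(seq_len(n), B)))
  split(perm, rep(seq_len(B), each = n))
}

#' Bootstrapped VIP statistics
#'
#' Refits the full pipeline (preprocessing, dummy response, PLS model) on B
#' balanced-bootstrap resamples of the experimental units (all time points of
#' a unit move together) and records, per variable, the mean (`VIP*`) and
#' standard deviation (`sigma_VIP`) of the B VIP values. Bootstrap sets in
#' which one group vanishes are redrawn (counted in the `n_redrawn`
#' attribute). With `rule = "loading_weight"` the statistic is the scaled
#' first-component loading weight `sqrt(J) |w_j1|` instead of the VIP.
#'
#' @param data a [long_table()] or (for models 4-5) a `data_cube`.
#' @param spec a [model_spec()].
#' @param design a [response_design()].
#' @param A number of latent variables (integer; use [cross_validate()] +
#'   [choose_n_latent()] to pick it).
#' @param B number of bootstrap sets (default 200, the smallest value found to
#'   give consistent selections).
#' @param seed integer seed; fixes the resampling exactly.
#' @param rule `"vip"` (default) or `"loading_weight"`.
#' @param component component used by the loading-weight rule (default 1).
#' @return A data.frame of class `vip_stats` with columns `variable_id`,
#'   `vip_mean`, `vip_sd`, `rank` (descending by mean) and `selected`
#'   (rule `VIP* - sigma_VIP > 1`), plus attributes `B`, `A`, `rule`,
#'   `n_redrawn`.
#' @seealso [select_variables()]
#' @export
bootstrap_vip <- function(data, spec, design = response_design(), A, B = 200L,
                          seed = NULL, rule = c("vip", "loading_weight"),
                          component = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  rule <- match.arg(rule)
  A <- as.integer(A)
  if (spec$x_shape == "trilinear" && inherits(data, "long_table"))
    data <- to_cube(data)
  if (spec$x_shape == "bilinear" && inherits(data, "data_cube"))
    data <- from_cube(data)

  if (spec$x_shape == "bilinear") {
    units <- sort(unique(data$samples$unit))
    group_of_unit <- data$samples$group[match(units, data$samples$unit)]
    rows_of_unit <- lapply(units, function(u) which(data$samples$unit == u))
    J <- ncol(data$X)
    variable_ids <- data$variable_ids
  } else {
    units <- data$unit_ids
    group_of_unit <- data$group
    d <- dim(data$X3)
    J <- d[2L]
    variable_ids <- data$variable_ids
    Ufull <- unfold_mode1(data$X3)
  }
  n <- length(units)
  if (n < 4L) stop("need at least 4 experimental units to bootstrap", call. = FALSE)
  Y <- make_dummy_y(data, spec, design)
  ymat <- if (is.matrix(Y)) Y else NULL

  seeds <- derive_seeds(seed, 2L)
  sets <- balanced_bootstrap_indices(n, B, seeds[1L])
  n_redrawn <- 0L
  stat <- matrix(NA_real_, J, B)
  with_seed(seeds[2L], {
    for (b in seq_len(B)) {
      idx <- sets[[b]]
      attempts <- 0L
      while (length(unique(as.integer(group_of_unit[idx]))) < 2L) {
        attempts <- attempts + 1L
        if (attempts > 50L)
          stop("resampling error: could not draw a bootstrap set containing both groups",
               call. = FALSE)
        idx <- sample.int(n, n, replace = TRUE)
        n_redrawn <- n_redrawn + (attempts == 1L)
      }
      if (spec$x_shape == "bilinear") {
        rows <- unlist(rows_of_unit[idx], use.names = FALSE)
        sc <- autoscale_tolerant(data$X[rows, , drop = FALSE])
        fit <- fit_pls(sc$X, Y[rows], A)
      } else {
        Ub <- Ufull[idx, , drop = FALSE]
        pp <- preprocess_unfolded(Ub, d[2L], d[3L])
        if (spec$y_variant == "trilinear_group") {
          fit <- npls1_core(pp$U, d[2L], d[3L], Y[idx], A)
          class(fit) <- "tripls_model"
        } else {
          cube_b <- subset_cube(data, idx)
          cube_b$X3 <- fold_mode1(pp$U, d[2L], d[3L])
          fit <- fit_npls2(cube_b, ymat[idx, , drop = FALSE], A)
        }
      }
      stat[, b] <- if (rule == "vip") vip(fit) else
        loading_weight_stat(fit, component)
    }
  })
  vip_mean <- rowMeans(stat)
  vip_sd <- if (B == 1L) rep(0, J) else apply(stat, 1L, stats::sd)
  out <- data.frame(variable_id = variable_ids,
                    vip_mean = vip_mean,
                    vip_sd = vip_sd,
                    rank = rank(-vip_mean, ties.method = "first"),
                    selected = vip_mean - vip_sd > 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("vip_stats", "data.frame")
  attr(out, "B") <- B; attr(out, "A") <- A
  attr(out, "rule") <- rule; attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Select variables from bootstrapped VIP statistics
#'
#' A variable is selected when the lower bound of its one-standard-deviation
#' error bar exceeds the threshold: `VIP* - sigma_VIP > threshold` (strict).
#'
#' @param stats a `vip_stats` data.frame from [bootstrap_vip()].
#' @param threshold selection threshold (default 1, the average-importance
#'   reference).
#' @return Integer vector of selected variable indices.
#' @export
select_variables <- function(stats, threshold = 1) {
  stopifnot(inherits(stats, "vip_stats"))
  which(stats$vip_mean - stats$vip_sd > threshold)
}

#' Select variables by bootstrapped first-component loading weights
#'
#' Alternative to the VIP rule that can be more powerful for trilinear models:
#' the statistic is the scaled loading weight `sqrt(J) |w_j1|`, whose squared
#' values average one, so the same threshold-1 rule shape applies to its
#' bootstrap mean minus standard deviation.
#'
#' @param stats a `vip_stats` object computed with
#'   `bootstrap_vip(..., rule = "loading_weight")`.
#' @param threshold selection threshold (default 1).
#' @return Integer vector of selected variable indices.
#' @export
select_by_loading_weight <- function(stats, threshold = 1) {
  stopifnot(inherits(stats, "vip_stats"))
  if (!identical(attr(stats, "rule"), "loading_weight"))
    stop("`stats` must be computed with rule = \"loading_weight\"", call. = FALSE)
  which(stats$vip_mean - stats$vip_sd > threshold)
}
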