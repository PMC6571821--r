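#' Configuration for the intervention time-series simulator
#'
#' The simulator emulates an acute intervention metabolomics study: two groups
#' (control / intervention) of S units each, sampled at a common time grid.
#' Each variable follows a pharmacokinetic-like mean curve
#' `mu_g(t) = c + a t^alpha exp(-beta t)` per group, multiplied by a subject
#' random term: a constant inter-individual offset (sd `sigma_b`), an AR(1)
#' intra-individual fluctuation (sd `sigma_w`, lag-1 correlation `rho`) and
#' i.i.d. measurement noise (sd `sigma_e`):
#' `x_s(t) = mu_g(t) * (1 + b_s + w_s(t) + e_s(t))`.
#'
#' Eight temporal-profile classes `a`-`h` determine how the control-group
#' curve relates to the intervention curve; classes `a`-`f` have
#' group-distinct mean curves (discriminating variables), class `g` shares one
#' curve across groups (a response unrelated to treatment) and class `h` is
#' flat in both groups (pure noise). See [profile_classes()].
#'
#' @param n_units_per_group units (subjects) per group S (default 10).
#' @param n_variables total number of variables J (default 3000).
#' @param n_discriminating number of discriminating variables (classes a-f;
#'   default 80).
#' @param times sampling time grid in hours (default `c(0, 2, 4, 24)`).
#' @param sigma_b inter-individual sd (default 0.3).
#' @param sigma_w intra-individual sd (default 0.2).
#' @param rho AR(1) correlation between consecutive time points, in `[0, 1)`
#'   (default 0.5).
#' @param sigma_e i.i.d. noise sd (default 0.1).
#' @param class_mix optional named vector of proportions over classes
#'   `a`-`h`; the default splits the discriminating variables uniformly over
#'   `a`-`f` and the remainder 20 percent class `g`, 80 percent class `h`
#'   (the shared-responder fraction implied by the reference benchmarks,
#'   where the time-response-only model selects about a fifth of the
#'   variables at every dataset size).
#'   Proportions over `a`-`f` must be consistent with `n_discriminating`.
#' @param seed integer seed making the dataset fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_units_per_group = 10L, n_variables = 3000L,
                       n_discriminating = 80L, times = c(0, 2, 4, 24),
                       sigma_b = 0.3, sigma_w = 0.2, rho = 0.5,
                       sigma_e = 0.1, class_mix = NULL, seed = NULL) {
  times <- sort(as.numeric(times))
  if (anyDuplicated(times)) stop("tied time points are not allowed", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (n_discriminating > n_variables)
    stop("config error: n_discriminating exceeds n_variables", call. = FALSE)
  if (rho < 0 || rho >= 1)
    stop("domain error: rho must lie in [0, 1)", call. = FALSE)
  if (min(sigma_b, sigma_w, sigma_e) < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  cfg <- structure(list(n_units_per_group = as.integer(n_units_per_group),
                        n_variables = as.integer(n_variables),
                        n_discriminating = as.integer(n_discriminating),
                        times = times, sigma_b = sigma_b, sigma_w = sigma_w,
                        rho = rho, sigma_e = sigma_e, class_mix = class_mix,
                        seed = seed),
                   class = "sim_config")
  class_counts(cfg)  # validates the mix
  cfg
}

#' Temporal-profile classes of the simulator
#'
#' Every responding variable follows `mu(t) = c (1 + R ghat(t))` where
#' `ghat(t) = t^alpha exp(-beta t)` is rescaled to peak height 1 over the
#' response window (the interior time points), `c ~ U(0.2, 1)` is the
#' baseline and `R` is the peak response as a fold-change over baseline. The
#' rise exponent `alpha ~ U(0.8, 2)` and decay rate `beta ~ U(0.3, 1.2)` set
#' the shape (peak near `alpha / beta` hours).
#'
#' Discriminating classes `a`-`f` are modest responders in the intervention
#' group (`R ~ U(1, 2)`) whose control-group curve differs per class:
#'
#' * `a` — control flat (no response; intervention-specific biomarker);
#' * `b` — control response strongly attenuated (`R x U(0.2, 0.5)`);
#' * `c` — control response mildly attenuated (`R x U(0.5, 0.8)`);
#' * `d` — control response of equal height decaying much faster
#'   (`beta x U(2, 3)`: back near baseline by the mid samples);
#' * `e` — control response smaller and peaking earlier
#'   (`R x U(0.4, 0.8)`, `alpha x U(0.4, 0.7)`);
#' * `f` — control response attenuated and prolonged
#'   (`R x U(0.3, 0.7)`, `beta x U(0.4, 0.8)`).
#'
#' The non-discriminating background mirrors what dominates real acute
#' intervention data: class `g` variables respond strongly but identically in
#' both groups (`R ~ U(2, 5)`, one shared draw — e.g. circadian or
#' postprandial excretion unrelated to treatment) and class `h` variables are
#' flat (`R = 0`) in both groups.
#'
#' @return data.frame with one row per class: `class`, `discriminating`,
#'   the intervention fold-change interval (`R_lo`, `R_hi`), and
#'   control-group multiplier intervals for `R`, `alpha` and `beta`.
#' @export
profile_classes <- function() {
  data.frame(
    class = letters[1:8],
    discriminating = c(rep(TRUE, 6L), FALSE, FALSE),
    R_lo     = c(1, 1, 1, 1, 1, 1, 4,  0),
    R_hi     = c(2, 2, 2, 2, 2, 2, 10, 0),
    ctrl_R_lo     = c(0, 0,    0.05, 0,    0.05, 0,    1, 1),
    ctrl_R_hi     = c(0, 0.1,  0.15, 0.1,  0.15, 0.1,  1, 1),
    ctrl_alpha_lo = c(1, 1,   1,   1,   0.4, 1,   1, 1),
    ctrl_alpha_hi = c(1, 1,   1,   1,   0.7, 1,   1, 1),
    ctrl_beta_lo  = c(1, 1,   1,   2,   1,   0.4, 1, 1),
    ctrl_beta_hi  = c(1, 1,   1,   3,   1,   0.8, 1, 1),
    stringsAsFactors = FALSE)
}

# Exact per-class variable counts for a config; errors if a user-supplied mix
# is inconsistent with the exact discriminating count.
class_counts <- function(cfg) {
  J <- cfg$n_variables; nd <- cfg$n_discriminating
  if (is.null(cfg$class_mix)) {
    disc <- rep(nd %/% 6L, 6L)
    extra <- nd %% 6L
    if (extra > 0L) disc[seq_len(extra)] <- disc[seq_len(extra)] + 1L
    ng <- round(0.2 * (J - nd))
    counts <- c(disc, ng, J - nd - ng)
  } else {
    mix <- cfg$class_mix[letters[1:8]]
    if (anyNA(mix) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      stop("config error: class_mix must be proportions over classes a-h summing to 1",
           call. = FALSE)
    base <- floor(mix * J)
    rem <- J - sum(base)
    if (rem > 0L) {
      frac <- mix * J - base
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1L
    }
    counts <- as.integer(base)
    if (sum(counts[1:6]) != nd)
      stop(sprintf("config error: class_mix implies %d discriminating variables but n_discriminating = %d",
                   sum(counts[1:6]), nd), call. = FALSE)
  }
  stats::setNames(as.integer(counts), letters[1:8])
}

#' Group mean curve of the simulator
#'
#' `mu(t) = c + a t^alpha exp(-beta t)`: baseline level `c`, response
#' amplitude `a`, rise exponent `alpha` (peak near `alpha / beta`), decay rate
#' `beta` per hour. `0^alpha` is 0 for `alpha > 0`.
#'
#' @param c,a,alpha,beta curve parameters (`beta >= 0`; `alpha > 0` whenever
#'   the grid contains `t = 0`).
#' @param times non-negative time grid.
#' @return Numeric vector `mu(times)`.
#' @export
mean_curve <- function(c, a, alpha, beta, times) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("domain error: times must be non-negative", call. = FALSE)
  if (beta < 0) stop("domain error: beta must be non-negative", call. = FALSE)
  if (alpha <= 0 && any(times == 0))
    stop("domain error: alpha <= 0 is undefined at t = 0", call. = FALSE)
  c + a * times^alpha * exp(-beta * times)
}

ar1_covariance <- function(sigma_w, rho, Tn) {
  sigma_w^2 * rho^abs(outer(seq_len(Tn), seq_len(Tn), "-"))
}

#' Draw subject-level random terms
#'
#' Draws the three stochastic components of the simulator for `n` subjects:
#' the constant inter-individual offset `b` (all-ones covariance
#' `sigma_b^2 * 1`, i.e. one normal draw repeated across the time grid), the
#' AR(1) intra-individual term `w` (covariance
#' `sigma_w^2 rho^|i - j|`) and i.i.d. noise `e` (sd `sigma_e`).
#'
#' @param config a [sim_config()].
#' @param n number of subject draws (rows).
#' @param seed optional integer seed.
#' @return List of three `n x T` matrices `b`, `w`, `e`.
#' @export
draw_subject_terms <- function(config, n = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  Tn <- length(config$times)
  with_seed(seed, {
    b <- matrix(stats::rnorm(n, sd = config$sigma_b), n, Tn)
    w <- if (config$sigma_w > 0)
      matrix(stats::rnorm(n * Tn), n, Tn) %*%
        chol(ar1_covariance(config$sigma_w, config$rho, Tn))
    else matrix(0, n, Tn)
    e <- matrix(stats::rnorm(n * Tn, sd = config$sigma_e), n, Tn)
    list(b = b, w = w, e = e)
  })
}

# Peak height of t^alpha exp(-beta t) over the response window (interior
# times; the full grid when there are fewer than three time points).
shape_peak <- function(alpha, beta, times) {
  win <- if (length(times) >= 3L) times[-c(1L, length(times))] else times
  win <- win[win > 0]
  pk <- rep(0, length(alpha))
  for (tt in win) pk <- pmax(pk, tt^alpha * exp(-beta * tt))
  pk
}

# Draw curve parameters for nv variables of one class. The amplitude `a` is
# derived from the fold-change R so that the curve peaks at c * (1 + R) over
# the response window: a = R * c / max_window(t^alpha e^{-beta t}). Returns a
# list of two data.frames (intervention, control) with columns c, a, alpha,
# beta.
draw_profile_params <- function(class_id, nv, times) {
  cls <- profile_classes()
  row <- cls[cls$class == class_id, ]
  cc <- stats::runif(nv, 0.2, 1)
  R <- stats::runif(nv, row$R_lo, row$R_hi)
  al <- stats::runif(nv, 0.8, 2)
  be <- if (row$discriminating) stats::runif(nv, 0.15, 1.2)
        else stats::runif(nv, 0.3, 1.2)
  int <- data.frame(c = cc, a = R * cc / shape_peak(al, be, times),
                    alpha = al, beta = be)
  if (class_id == "h") int$a <- rep(0, nv)
  if (class_id %in% c("g", "h")) {
    ctrl <- int
  } else {
    Rc <- R * stats::runif(nv, row$ctrl_R_lo, row$ctrl_R_hi)
    alc <- al * stats::runif(nv, row$ctrl_alpha_lo, row$ctrl_alpha_hi)
    bec <- be * stats::runif(nv, row$ctrl_beta_lo, row$ctrl_beta_hi)
    ctrl <- data.frame(c = cc, a = Rc * cc / shape_peak(alc, bec, times),
                       alpha = alc, beta = bec)
  }
  list(intervention = int, control = ctrl)
}

#' Simulate one variable
#'
#' @param class_id profile class, one of `letters[1:8]`.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return List with `control` and `intervention` (`S x T` matrices of
#'   simulated intensities) and `truth` (one-row data.frame with the class,
#'   discriminating flag and drawn curve parameters per group).
#' @export
simulate_variable <- function(class_id, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), class_id %in% letters[1:8])
  with_seed(seed, {
    par <- draw_profile_params(class_id, 1L, config$times)
    S <- config$n_units_per_group
    out <- lapply(c(control = "control", intervention = "intervention"),
                  function(g) {
      p <- par[[g]]
      mu <- mean_curve(p$c, p$a, p$alpha, p$beta, config$times)
      terms <- draw_subject_terms(config, S)
      sweep(1 + terms$b + terms$w + terms$e, 2L, mu, "*")
    })
    out$truth <- data.frame(class = class_id,
                            discriminating = class_id %in% letters[1:6],
                            c = par$intervention$c,
                            a_int = par$intervention$a,
                            alpha_int = par$intervention$alpha,
                            beta_int = par$intervention$beta,
                            a_ctrl = par$control$a,
                            alpha_ctrl = par$control$alpha,
                            beta_ctrl = par$control$beta,
                            stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a complete intervention time-series dataset
#'
#' Generates J variables with profile classes assigned per the configured mix
#' (the discriminating count is realized exactly), for 2S experimental units
#' (S per group) over the configured time grid. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `table` (a [long_table()]), `cube` (the matching
#'   `data_cube`) and `truth` (data.frame of class `sim_truth`: one row per
#'   variable with `variable_id`, `class`, `discriminating`, and the drawn
#'   curve parameters per group).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- class_counts(config)
  S <- config$n_units_per_group
  Sn <- 2L * S
  Tn <- length(config$times)
  J <- config$n_variables
  classes <- rep(names(counts), counts)
  with_seed(config$seed, {
    # curve parameters per variable, drawn class by class
    mu_int <- matrix(0, J, Tn); mu_ctrl <- matrix(0, J, Tn)
    truth <- vector("list", 8L)
    for (k in seq_along(counts)) {
      nv <- counts[k]
      if (nv == 0L) next
      idx <- which(classes == names(counts)[k])
      par <- draw_profile_params(names(counts)[k], nv, config$times)
      for (ti in seq_len(Tn)) {
        tt <- config$times[ti]
        mu_int[idx, ti] <- par$intervention$c + par$intervention$a *
          tt^par$intervention$alpha * exp(-par$intervention$beta * tt)
        mu_ctrl[idx, ti] <- par$control$c + par$control$a *
          tt^par$control$alpha * exp(-par$control$beta * tt)
      }
      truth[[k]] <- data.frame(variable_id = sprintf("V%04d", idx),
                               class = names(counts)[k],
                               discriminating = names(counts)[k] %in% letters[1:6],
                               c = par$intervention$c,
                               a_int = par$intervention$a,
                               alpha_int = par$intervention$alpha,
                               beta_int = par$intervention$beta,
                               a_ctrl = par$control$a,
                               alpha_ctrl = par$control$alpha,
                               beta_ctrl = par$control$beta,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$variable_id), ]
    rownames(truth) <- NULL
    class(truth) <- c("sim_truth", "data.frame")

    # units: C01..CS control then I01..IS intervention (sorted cube order)
    unit_ids <- c(sprintf("C%02d", seq_len(S)), sprintf("I%02d", seq_len(S)))
    group <- factor(rep(c("control", "intervention"), each = S),
                    levels = c("control", "intervention"))

    # random terms per (unit, variable) pair; row index s + (u - 1) * Sn
    npair <- Sn * J
    b <- stats::rnorm(npair, sd = config$sigma_b)
    W <- if (config$sigma_w > 0)
      matrix(stats::rnorm(npair * Tn), npair, Tn) %*%
        chol(ar1_covariance(config$sigma_w, config$rho, Tn))
    else matrix(0, npair, Tn)
    E <- matrix(stats::rnorm(npair * Tn, sd = config$sigma_e), npair, Tn)

    X3 <- array(0, dim = c(Sn, J, Tn),
                dimnames = list(unit_ids, sprintf("V%04d", seq_len(J)),
                                config$times))
    ctrl_rows <- as.integer(group) == 1L
    for (ti in seq_len(Tn)) {
      mu_slice <- rbind(matrix(mu_ctrl[, ti], nrow = S, ncol = J, byrow = TRUE),
                        matrix(mu_int[, ti], nrow = S, ncol = J, byrow = TRUE))
      noise <- matrix(b + W[, ti] + E[, ti], Sn, J)
      X3[, , ti] <- mu_slice * (1 + noise)
    }
    cube <- structure(list(X3 = X3, unit_ids = unit_ids,
                           variable_ids = sprintf("V%04d", seq_len(J)),
                           times = config$times, group = group,
                           subjects = unit_ids),
                      class = "data_cube")
    list(table = from_cube(cube), cube = cube, truth = truth)
  })
}

#' Simulate a paired training and test dataset
#'
#' Simulates one dataset with twice the configured number of subjects per
#' group and divides it into training and test halves at the unit level, the
#' way a single study cohort is split: both halves share the same variables
#' (identical curve parameters and truth labels) and differ only in their
#' subjects' random terms. The training half has `config$n_units_per_group`
#' units per group.
#'
#' @param config a [sim_config()].
#' @return List with `train` and `test` (each a list `table`, `cube`) and the
#'   shared `truth`.
#' @export
simulate_train_test <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  big <- config
  big$n_units_per_group <- 2L * config$n_units_per_group
  sim <- simulate_dataset(big)
  S <- config$n_units_per_group
  num <- as.integer(sub("^[CI]", "", sim$cube$unit_ids))
  tr <- which(num <= S)
  te <- which(num > S)
  cube_tr <- subset_cube(sim$cube, tr)
  cube_te <- subset_cube(sim$cube, te)
  list(train = list(table = from_cube(cube_tr), cube = cube_tr),
       test = list(table = from_cube(cube_te), cube = cube_te),
       truth = sim$truth)
}
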