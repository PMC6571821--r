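# Small in-code fixtures shared across test files.

# Complete-design long table with random intensities: S units per group,
# labelled so that intervention units sort first (i01, i02, ..., then k01...).
toy_table <- function(S_per_group = 2, J = 3, times = c(0, 2, 4, 24),
                      seed = 1) {
  set.seed(seed)
  Sn <- 2 * S_per_group
  Tn <- length(times)
  unit <- rep(c(sprintf("i%02d", seq_len(S_per_group)),
                sprintf("k%02d", seq_len(S_per_group))), each = Tn)
  group <- rep(c("intervention", "control"), each = S_per_group * Tn)
  long_table(matrix(rnorm(Sn * Tn * J), Sn * Tn, J),
             subject = unit, group = group, time = rep(times, Sn),
             unit = unit, variable_ids = paste0("V", seq_len(J)))
}

# Noise-free rank-1 cube: X_s = t0_s * u v', plus the factors used.
rank1_cube <- function(Sn = 6, J = 5, Tn = 4, seed = 1) {
  set.seed(seed)
  u <- rnorm(J); u <- u / sqrt(sum(u^2))
  if (u[which.max(abs(u))] < 0) u <- -u
  v <- rnorm(Tn); v <- v / sqrt(sum(v^2))
  t0 <- rnorm(Sn)
  t0 <- t0 - mean(t0)
  X3 <- array(0, dim = c(Sn, J, Tn))
  for (s in seq_len(Sn)) X3[s, , ] <- t0[s] * tcrossprod(u, v)
  cube <- structure(list(X3 = X3, unit_ids = sprintf("u%02d", seq_len(Sn)),
                         variable_ids = paste0("V", seq_len(J)),
                         times = seq_len(Tn) - 1,
                         group = factor(rep(c("control", "intervention"),
                                            length.out = Sn),
                                        levels = c("control", "intervention")),
                         subjects = sprintf("u%02d", seq_len(Sn))),
                    class = "data_cube")
  list(cube = cube, u = u, v = v, t0 = t0)
}

# Random centred cube.
random_cube <- function(Sn = 6, J = 4, Tn = 3, seed = 1) {
  set.seed(seed)
  X3 <- array(rnorm(Sn * J * Tn), dim = c(Sn, J, Tn))
  structure(list(X3 = X3, unit_ids = sprintf("u%02d", seq_len(Sn)),
                 variable_ids = paste0("V", seq_len(J)),
                 times = seq_len(Tn) - 1,
                 group = factor(rep(c("control", "intervention"),
                                    length.out = Sn),
                                levels = c("control", "intervention")),
                 subjects = sprintf("u%02d", seq_len(Sn))),
            class = "data_cube")
}

# Hand-made vip_stats object for testing the selection rules.
fake_vip_stats <- function(vip_mean, vip_sd, rule = "vip") {
  out <- data.frame(variable_id = paste0("V", seq_along(vip_mean)),
                    vip_mean = vip_mean, vip_sd = vip_sd,
                    rank = rank(-vip_mean, ties.method = "first"),
                    selected = vip_mean - vip_sd > 1)
  class(out) <- c("vip_stats", "data.frame")
  attr(out, "B") <- 1L; attr(out, "A") <- 1L
  attr(out, "rule") <- rule; attr(out, "n_redrawn") <- 0L
  out
}
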