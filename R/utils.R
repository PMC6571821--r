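# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Unfold an S' x J x T array into S' x (J*T); column (t-1)*J + j holds
# variable j at time t, so the column weight vector is kronecker(wK, wJ).
unfold_mode1 <- function(X3) {
  d <- dim(X3)
  matrix(X3, nrow = d[1L], ncol = d[2L] * d[3L])
}

fold_mode1 <- function(U, J, Tn) {
  array(U, dim = c(nrow(U), J, Tn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
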