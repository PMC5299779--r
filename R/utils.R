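# internal numerical helpers

# Row-wise log-sum-exp of a matrix of log-densities.
logsumexp_rows <- function(lm) {
  m <- apply(lm, 1L, max)
  bad <- !is.finite(m)
  if (any(bad)) m[bad] <- 0
  m + log(rowSums(exp(lm - m)))
}

# Deterministic stage seed derived from a master seed and a stage name.
# Adding a stage never perturbs another stage's stream.  Kept below 2^31.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 31L + h * 7919) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Check that each row of `m` is a probability simplex.
is_simplex_rows <- function(m, tol = 1e-8) {
  all(m >= -tol) && all(abs(rowSums(m) - 1) < 1e-6)
}
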