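# Independent brute-force oracles used across test files.

# KDIGO staging written as an independent rule table: evaluate every
# criterion separately and take the maximum applicable stage.
oracle_kdigo <- function(b, m48, m7, rrt) {
  stages <- c(
    if (m48 - b - 0.3 >= 0) 1L else 0L,
    if (m7 - 1.5 * b >= 0) 1L else 0L,
    if (m7 - 2.0 * b >= 0) 2L else 0L,
    if (m7 - 3.0 * b >= 0) 3L else 0L,
    if (m7 - 4.0 >= 0) 3L else 0L,
    if (rrt) 3L else 0L)
  max(stages)
}

# Exact two-sided sign-test p by full enumeration of all 2^n equally likely
# win/loss sequences.
oracle_sign_test <- function(wins, n) {
  seqs <- expand.grid(rep(list(0:1), n))
  counts <- rowSums(seqs)
  p_le <- mean(counts <= wins)
  p_ge <- mean(counts >= wins)
  min(1, 2 * min(p_le, p_ge))
}

# Exact permutation p for the paired Spearman test by enumerating all 2^n
# per-subject label-swap patterns.
oracle_spearman_perm_p <- function(pred_a, pred_b, observed) {
  n <- length(observed)
  rho <- function(a) suppressWarnings(
    stats::cor(a, observed, method = "spearman"))
  delta <- rho(pred_a) - rho(pred_b)
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  deltas <- apply(swaps, 1L, function(sw) {
    pa <- ifelse(sw, pred_b, pred_a)
    pb <- ifelse(sw, pred_a, pred_b)
    rho(pa) - rho(pb)
  })
  mean(abs(deltas) >= abs(delta) - 1e-12)
}

# Closed-form power of the two-sided t-test for the slope of a simple linear
# regression with known generating slope/noise (noncentral-t).
oracle_slope_power <- function(x, beta, sigma, alpha = 0.05) {
  n <- length(x)
  df <- n - 2
  sxx <- sum((x - mean(x))^2)
  ncp <- beta * sqrt(sxx) / sigma
  tq <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tq, df, ncp) + stats::pt(tq, df, ncp, lower.tail = FALSE)
}

# Normal-equations least squares by explicit matrix inversion.
oracle_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# A tiny deterministic regression problem used by several mixture tests.
tiny_design <- function(n, seed = 1, p = 2) {
  set.seed(seed)
  cbind(`(Intercept)` = 1,
        matrix(rnorm(n * p), n, p,
               dimnames = list(NULL, paste0("x", seq_len(p)))))
}

# Simulate a clearly separated two-component univariate mixture of
# regressions; returns design, outcome and the generating truth.
separated_mixture_data <- function(n, seed = 1, pi1 = 0.3,
                                   beta1 = c(0, 1), beta2 = c(2, -1),
                                   sigma = 0.05) {
  set.seed(seed)
  x <- runif(n, -1, 1)
  X <- cbind(`(Intercept)` = 1, x = x)
  z <- ifelse(runif(n) < pi1, 1L, 2L)
  mu <- ifelse(z == 1L, beta1[1] + beta1[2] * x, beta2[1] + beta2[2] * x)
  y <- mu + rnorm(n, 0, sigma)
  list(X = X, y = y, z = z, pi1 = pi1, beta1 = beta1, beta2 = beta2,
       sigma = sigma)
}
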