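# K-component Gaussian mixture of linear regressions, fit by EM with random
# responsibility initialization and multiple restarts.
#
# Model: y_i | x_i ~ sum_k pi_k N(x_i' beta_k, sigma_k^2).  The E-step
# computes responsibilities r_ik (posterior component membership), the M-step
# refits each component by responsibility-weighted least squares.

#' E-step: responsibilities and observed-data log-likelihood
#'
#' Computes `r_ik = pi_k N(y_i; x_i' beta_k, sigma_k^2) / sum_l ...` with
#' log-sum-exp stabilization, and the observed-data log-likelihood.
#'
#' @param pi Mixing-weight simplex of length K.
#' @param components List of K lists with elements `beta` and `sigma2`.
#' @param X Design matrix including the intercept column.
#' @param y Outcome vector.
#' @return List with `responsibilities` (n x K, rows summing to 1) and
#'   `loglik`.
#' @export
e_step <- function(pi, components, X, y) {
  K <- length(components)
  n <- length(y)
  logdens <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    mu <- drop(X %*% components[[k]]$beta)
    logdens[, k] <- log(pi[k]) +
      stats::dnorm(y, mu, sqrt(components[[k]]$sigma2), log = TRUE)
  }
  lse <- logsumexp_rows(logdens)
  if (any(!is.finite(lse)))
    stop("zero total mixture density for subject(s) ",
         paste(utils::head(which(!is.finite(lse)), 5L), collapse = ", "),
         call. = FALSE)
  r <- exp(logdens - lse)
  list(responsibilities = r, loglik = sum(lse))
}

#' M-step: weighted least-squares refit of each component
#'
#' For each component, solves the responsibility-weighted least-squares
#' problem for `beta_k`, sets `sigma_k^2` to the weighted mean squared
#' residual (floored at `variance_floor`), and updates `pi_k` to the mean
#' responsibility.
#'
#' @param responsibilities n x K matrix with rows summing to 1.
#' @param X Design matrix with intercept.
#' @param y Outcome vector.
#' @param variance_floor Lower bound for component variances.
#' @return List with `pi` and `components` (each with `beta`, `sigma2`,
#'   `weight` = total responsibility).
#' @export
m_step <- function(responsibilities, X, y, variance_floor = 1e-10) {
  K <- ncol(responsibilities)
  p1 <- ncol(X)
  components <- vector("list", K)
  for (k in seq_len(K)) {
    w <- responsibilities[, k]
    sw <- sum(w)
    if (sw <= p1)
      stop(sprintf("component %d degenerate: effective weight %.3f <= %d",
                   k, sw, p1), call. = FALSE)
    fit <- stats::lm.wfit(X, y, w)
    if (fit$rank < p1)
      stop(sprintf("singular weighted design in component %d", k),
           call. = FALSE)
    res <- y - drop(X %*% fit$coefficients)
    components[[k]] <- list(beta = fit$coefficients,
                            sigma2 = max(sum(w * res^2) / sw, variance_floor),
                            weight = sw)
  }
  list(pi = colMeans(responsibilities), components = components)
}

#' Default EM configuration
#'
#' @param n_restarts Random restarts (each from fresh Dirichlet(1,..,1)
#'   responsibilities).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Absolute log-likelihood change declaring convergence.
#' @param variance_floor_frac Variance floor as a fraction of `var(y)`.
#' @param min_weight Mixing weight below which the fit is collapsed to the
#'   single-component (OLS) model.  The 0.05 default guards against
#'   small-variance spike components (a handful of subjects fit almost
#'   exactly by a p-parameter component, the classic unbounded-likelihood
#'   degeneracy of Gaussian mixtures).
#' @param seed Integer seed for the random initializations.
#' @return List of settings for [fit_mixture()].
#' @export
mixture_control <- function(n_restarts = 20L, max_iter = 1000L, tol = 1e-8,
                            variance_floor_frac = 1e-6, min_weight = 0.05,
                            seed = 1L) {
  list(n_restarts = as.integer(n_restarts), max_iter = as.integer(max_iter),
       tol = tol, variance_floor_frac = variance_floor_frac,
       min_weight = min_weight, seed = as.integer(seed))
}

# one EM run from an initial responsibility matrix; returns fit + trace
run_em <- function(r, X, y, K, control, variance_floor) {
  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  pi <- NULL; components <- NULL
  for (iter in seq_len(control$max_iter)) {
    m <- m_step(r, X, y, variance_floor)
    e <- e_step(m$pi, m$components, X, y)
    r <- e$responsibilities
    trace <- c(trace, e$loglik)
    if (is.finite(loglik) && abs(e$loglik - loglik) < control$tol) {
      loglik <- e$loglik
      pi <- m$pi; components <- m$components
      converged <- TRUE
      break
    }
    loglik <- e$loglik
    pi <- m$pi; components <- m$components
  }
  list(pi = pi, components = components, responsibilities = r,
       loglik = loglik, trace = trace, n_iter = length(trace),
       converged = converged)
}

#' Fit a K-component mixture of linear regressions by EM
#'
#' Each restart draws every subject's initial responsibility vector from a
#' flat Dirichlet, runs EM to convergence, and the restart with the highest
#' log-likelihood wins.  Components are ordered by ascending mixing weight
#' (ties by descending coefficient L2 norm) so the minority subpopulation is
#' always component 1.  If any converged mixing weight falls below
#' `min_weight`, the fit collapses: component 1 becomes the OLS fit on all
#' data and the remaining components' coefficients are set to zero and
#' flagged degenerate.
#'
#' @param X Design matrix with intercept column (n x (p+1)).
#' @param y Outcome vector.
#' @param K Number of components (>= 1).
#' @param control A [mixture_control()] list.
#' @param init Optional n x K responsibility matrix to warm-start a single
#'   EM run (no random restarts); used by bootstrap refits.
#' @return An object of class `mixture_fit`.
#' @export
fit_mixture <- function(X, y, K = 2L, control = mixture_control(),
                        init = NULL) {
  n <- length(y)
  p1 <- ncol(X)
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (n <= K * (p1 + 1L))
    stop("too few observations for the requested number of components",
         call. = FALSE)
  variance_floor <- control$variance_floor_frac * stats::var(y)

  best <- NULL
  n_restarts_used <- 0L
  if (K == 1L) {
    best <- run_em(matrix(1, n, 1L), X, y, K, control, variance_floor)
    n_restarts_used <- 1L
  } else if (!is.null(init)) {
    stopifnot(nrow(init) == n, ncol(init) == K)
    best <- run_em(init, X, y, K, control, variance_floor)
    n_restarts_used <- 1L
  } else {
    set.seed(control$seed)
    for (s in seq_len(control$n_restarts)) {
      g <- matrix(stats::rexp(n * K), n, K)
      r0 <- g / rowSums(g)
      run <- tryCatch(run_em(r0, X, y, K, control, variance_floor),
                      error = function(e) NULL)
      if (is.null(run)) next
      n_restarts_used <- n_restarts_used + 1L
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    if (is.null(best))
      stop("no EM restart completed; data may be degenerate", call. = FALSE)
  }

  # deterministic component ordering: ascending pi, ties by descending
  # coefficient L2 norm
  ord <- order(best$pi, -vapply(best$components,
                                function(cp) sum(cp$beta^2), 0))
  best$pi <- best$pi[ord]
  best$components <- best$components[ord]
  best$responsibilities <- best$responsibilities[, ord, drop = FALSE]

  degenerate <- K > 1L && any(best$pi < control$min_weight)
  if (degenerate) {
    ols <- fit_ols(X, y)
    comp1 <- list(beta = ols$beta, sigma2 = ols$sigma2_mle, weight = n)
    zero <- list(beta = setNames(numeric(p1), colnames(X)), sigma2 = NA_real_,
                 weight = 0)
    best$components <- c(list(comp1), rep(list(zero), K - 1L))
    best$pi <- c(1, rep(0, K - 1L))
    best$responsibilities <- cbind(rep(1, n),
                                   matrix(0, n, K - 1L))
    best$loglik <- ols$loglik
  }

  structure(list(
    components = lapply(best$components, function(cp)
      list(beta = cp$beta, sigma2 = cp$sigma2, weight = cp$weight,
           se = NULL, p = NULL)),
    pi = best$pi,
    responsibilities = best$responsibilities,
    loglik = best$loglik,
    bic = mixture_bic(best$loglik, n, p1 - 1L, K),
    n_iter = best$n_iter,
    converged = best$converged,
    trace = best$trace,
    n_restarts_used = n_restarts_used,
    degenerate = degenerate,
    K = K, n = n,
    terms = colnames(X),
    seed = if (K > 1L && is.null(init)) control$seed else NA_integer_
  ), class = "mixture_fit")
}

#' BIC of a K-component mixture of regressions
#'
#' `BIC = -2 loglik + q log(n)` with `q = K (p + 2) + (K - 1)`: each
#' component carries p covariate coefficients, an intercept and a variance,
#' plus K - 1 free mixing weights.
#'
#' @param loglik Maximized log-likelihood.
#' @param n Number of subjects.
#' @param p Number of covariate terms excluding the intercept.
#' @param K Number of components.
#' @return BIC value.
#' @export
mixture_bic <- function(loglik, n, p, K) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  q <- K * (p + 2) + (K - 1)
  -2 * loglik + q * log(n)
}

#' Approximate per-component inference for a mixture fit
#'
#' Standard errors from the weighted-least-squares covariance
#' `(X' W_k X)^{-1} sigma_k^2` with `W_k = diag(r_ik)` and the
#' degrees-of-freedom-adjusted variance `sum_i r_ik e_ik^2 / (sum_i r_ik -
#' p - 1)`, and two-sided p-values from a t distribution with
#' `sum_i r_ik - (p+1)` degrees of freedom.  With unit responsibilities this
#' reduces exactly to classical OLS inference.  The standard errors ignore
#' the uncertainty in the responsibilities and are flagged approximate in
#' the fit metadata.
#'
#' @param fit A converged, non-degenerate `mixture_fit`.
#' @param X,y The data the fit was computed on.
#' @return The fit with `se` and `p` filled per component and
#'   `inference = "weighted-information (approximate)"`.
#' @export
component_inference <- function(fit, X, y) {
  if (isTRUE(fit$degenerate))
    stop("inference refused: the mixture collapsed to a single component; ",
         "use the linear-model fit instead", call. = FALSE)
  if (!isTRUE(fit$converged))
    stop("inference refused: EM did not converge", call. = FALSE)
  p1 <- ncol(X)
  for (k in seq_len(fit$K)) {
    w <- fit$responsibilities[, k]
    xtwx <- crossprod(X * sqrt(w))
    df <- max(sum(w) - p1, 1)
    sigma2_unb <- fit$components[[k]]$sigma2 * sum(w) / df
    se <- sqrt(diag(solve(xtwx)) * sigma2_unb)
    tval <- fit$components[[k]]$beta / se
    fit$components[[k]]$se <- se
    fit$components[[k]]$p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    fit$components[[k]]$df <- df
  }
  fit$inference <- "weighted-information (approximate)"
  fit
}

#' Membership-weighted mixture prediction
#'
#' `yhat_i = sum_k m_ik x_i' beta_k` for membership probabilities `m`
#' (e.g. fitted responsibilities in-sample, or outcome-blind classifier
#' probabilities out-of-sample).
#'
#' @param fit A `mixture_fit`.
#' @param X Design matrix with intercept.
#' @param membership_probs n x K matrix of simplex rows in the fit's
#'   component order.
#' @return Numeric vector of predicted outcomes.
#' @export
predict_weighted <- function(fit, X, membership_probs) {
  membership_probs <- as.matrix(membership_probs)
  if (ncol(membership_probs) != fit$K)
    stop("membership matrix has wrong number of components", call. = FALSE)
  if (!is_simplex_rows(membership_probs))
    stop("membership rows must be probability simplexes", call. = FALSE)
  B <- vapply(fit$components, function(cp) cp$beta, numeric(ncol(X)))
  rowSums(membership_probs * (X %*% B))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component mixture of linear regressions (n = %d)\n",
              x$K, x$n))
  cat(sprintf("  mixing weights: %s\n",
              paste(sprintf("%.3f", x$pi), collapse = ", ")))
  cat(sprintf("  loglik %.3f, BIC %.3f, %d iterations, converged: %s%s\n",
              x$loglik, x$bic, x$n_iter, x$converged,
              if (isTRUE(x$degenerate)) " [collapsed to single component]"
              else ""))
  invisible(x)
}

#' Serialize a mixture fit to JSON
#'
#' Coefficients are named by covariate, and the convergence trace and seeds
#' are retained so a fit artifact is reproducible and diffable.
#'
#' @param fit A `mixture_fit` (or `linear_fit`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- unclass(fit)
  obj$responsibilities <- NULL # optionally written separately as CSV
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                       na = "null", pretty = TRUE)
  invisible(path)
}
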