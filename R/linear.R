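# Ordinary least-squares baseline sharing the mixture's covariate-scaling
# conventions and its BIC definition (MLE variance inside the likelihood).

#' Fit the linear baseline model
#'
#' Exact least squares with classical t-test inference
#' (`df = n - p - 1`, unbiased residual variance for standard errors).  The
#' log-likelihood and BIC use the maximum-likelihood variance (`RSS / n`) so
#' that the model is exactly the K = 1 special case of the mixture and the
#' two BICs are comparable.
#'
#' @param X Design matrix with intercept column, full rank.
#' @param y Outcome vector, `length(y) > ncol(X)`.
#' @return An object of class `linear_fit` with elements `beta`, `sigma2`
#'   (unbiased), `sigma2_mle`, `se`, `p`, `loglik`, `bic`.
#' @export
fit_ols <- function(X, y) {
  n <- length(y)
  p1 <- ncol(X)
  if (n <= p1)
    stop("need more observations than coefficients", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p1) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p1]]
    stop("singular fit; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df <- n - p1
  sigma2 <- rss / df
  sigma2_mle <- rss / n
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- setNames(sqrt(diag(xtx_inv) * sigma2), colnames(X))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  loglik <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
  structure(list(beta = beta, sigma2 = sigma2, sigma2_mle = sigma2_mle,
                 se = se, p = p, df = df, loglik = loglik,
                 bic = mixture_bic(loglik, n, p1 - 1L, 1L),
                 n = n, terms = colnames(X)),
            class = "linear_fit")
}

#' Predict from a linear fit
#' @param object A `linear_fit`.
#' @param X Design matrix with intercept.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.linear_fit <- function(object, X, ...) drop(X %*% object$beta)

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear model (n = %d, %d terms)\n", x$n, length(x$beta) - 1L))
  cat(sprintf("  loglik %.3f, BIC %.3f, residual sd %.4f\n",
              x$loglik, x$bic, sqrt(x$sigma2)))
  invisible(x)
}
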