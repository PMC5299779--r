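# Model-comparison metrics: calibration, BIC relative likelihood, paired
# Spearman permutation test, relative MSE reduction, Q-Q error normality,
# and optimism-corrected bootstrap validation.

#' Calibration r-squared of predicted versus observed outcome
#'
#' Squared Pearson correlation of predictions against observations (the
#' scalar summary of a calibration plot).
#'
#' @param predicted,observed Equal-length numeric vectors, n >= 3.
#' @return Value in \[0, 1\].
#' @export
calibration_r2 <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 3L)
    stop("need aligned vectors with n >= 3", call. = FALSE)
  if (stats::sd(observed) == 0)
    stop("observed outcome is constant; calibration undefined", call. = FALSE)
  if (stats::sd(predicted) == 0) return(0)
  stats::cor(predicted, observed)^2
}

#' Relative likelihood of model a over model b from their BICs
#'
#' `exp((bic_b - bic_a) / 2)`: the evidence ratio favoring model a.  When the
#' ratio overflows double precision the log-scale value is returned with
#' attribute `log_scale = TRUE`.
#'
#' @param bic_a,bic_b Finite BIC values.
#' @return Positive evidence ratio (or its log, flagged).
#' @export
relative_likelihood <- function(bic_a, bic_b) {
  stopifnot_scalar_number(bic_a, "bic_a")
  stopifnot_scalar_number(bic_b, "bic_b")
  half <- (bic_b - bic_a) / 2
  out <- exp(half)
  if (!is.finite(out)) {
    out <- half
    attr(out, "log_scale") <- TRUE
  }
  out
}

#' Permutation test of paired Spearman correlations
#'
#' Tests whether model a's Spearman correlation between predicted and
#' observed outcome exceeds model b's.  The null is built by swapping, per
#' subject with probability 1/2, which model each prediction pair member is
#' attributed to; this preserves the outcome and each subject's pair of
#' predictions while destroying the model identity.  The two-sided p-value
#' uses the add-one correction `(1 + #{|delta*| >= |delta|}) / (n_perm + 1)`.
#'
#' @param pred_a,pred_b,observed Aligned numeric vectors.
#' @param n_perm Number of label-swap permutations (>= 1000 advised).
#' @param seed Integer seed.
#' @return List with `rho_a`, `rho_b`, `delta`, `p`, `n_perm`.
#' @export
spearman_perm_test <- function(pred_a, pred_b, observed, n_perm = 10000L,
                               seed = 1L) {
  n <- length(observed)
  if (length(pred_a) != n || length(pred_b) != n)
    stop("prediction vectors must align with `observed`", call. = FALSE)
  if (length(unique(observed)) < 2L)
    stop("observed vector is all ties; ranks undefined", call. = FALSE)
  rho <- function(a) suppressWarnings(stats::cor(a, observed,
                                                 method = "spearman"))
  rho_a <- rho(pred_a)
  rho_b <- rho(pred_b)
  delta <- rho_a - rho_b
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    sw <- stats::runif(n) < 0.5
    pa <- ifelse(sw, pred_b, pred_a)
    pb <- ifelse(sw, pred_a, pred_b)
    d <- rho(pa) - rho(pb)
    if (abs(d) >= abs(delta) - 1e-12) exceed <- exceed + 1L
  }
  list(rho_a = rho_a, rho_b = rho_b, delta = delta,
       p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Relative mean-squared-error reduction of model a versus model b
#'
#' `(MSE_b - MSE_a) / MSE_b`; positive when model a predicts more
#' accurately, at most 1.
#'
#' @param pred_a,pred_b,observed Aligned numeric vectors.
#' @return Relative reduction (unitless; multiply by 100 for percent).
#' @export
relative_mse_reduction <- function(pred_a, pred_b, observed) {
  n <- length(observed)
  if (length(pred_a) != n || length(pred_b) != n)
    stop("prediction vectors must align with `observed`", call. = FALSE)
  mse_a <- mean((pred_a - observed)^2)
  mse_b <- mean((pred_b - observed)^2)
  if (mse_b == 0)
    stop("reference model has zero MSE; relative reduction undefined",
         call. = FALSE)
  (mse_b - mse_a) / mse_b
}

#' Q-Q deviation of residuals from normality
#'
#' One minus the squared Filliben probability-plot correlation between the
#' sorted standardized residuals and the normal order-statistic medians.
#' Zero means the Q-Q plot lies exactly on its line; larger values mean
#' heavier departure from normal errors.  Location-scale invariant.
#'
#' @param residuals Numeric vector, n >= 10.
#' @return Deviation in \[0, 1\].
#' @export
qq_deviation <- function(residuals) {
  n <- length(residuals)
  if (n < 10L) stop("need at least 10 residuals", call. = FALSE)
  if (stats::sd(residuals) == 0)
    stop("constant residuals; Q-Q correlation undefined", call. = FALSE)
  u <- (seq_len(n) - 0.3175) / (n + 0.365)
  u[1L] <- 1 - 0.5^(1 / n)
  u[n] <- 0.5^(1 / n)
  m <- stats::qnorm(u)
  r <- stats::cor(sort(residuals), m)
  1 - r^2
}

#' Posterior-weighted standardized residuals of a mixture fit
#'
#' `e_i = (y_i - sum_k r_ik x_i' beta_k) / sqrt(sum_k r_ik sigma_k^2)`.
#'
#' @param fit A `mixture_fit`.
#' @param X Design matrix with intercept.
#' @param y Outcome vector.
#' @return Numeric vector of standardized residuals.
#' @export
mixture_residuals <- function(fit, X, y) {
  yhat <- predict_weighted(fit, X, fit$responsibilities)
  s2 <- drop(fit$responsibilities %*%
               vapply(fit$components, function(cp) cp$sigma2, 0))
  (y - yhat) / sqrt(s2)
}

#' Optimism-corrected bootstrap validation
#'
#' Harrell-style internal validation: for each bootstrap resample the fitter
#' is refit, evaluated on its own resample (apparent) and on the original
#' data; optimism is the mean apparent-minus-original gap and the corrected
#' metric is the full-sample apparent value minus that optimism.
#'
#' @param X Design matrix with intercept column.
#' @param y Outcome vector.
#' @param fitter Function `(X, y) -> function(X_new) predictions`; e.g. an
#'   OLS wrapper or the mixture + membership-classifier pipeline.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with apparent, optimism and corrected r2/mse, plus the
#'   failed-replicate count.
#' @export
bootstrap_validate <- function(X, y, fitter, B = 200L, seed = 1L) {
  n <- length(y)
  predict_full <- fitter(X, y)
  app_r2 <- calibration_r2(predict_full(X), y)
  app_mse <- mean((predict_full(X) - y)^2)
  set.seed(seed)
  opt_r2 <- opt_mse <- numeric(0)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    pf <- tryCatch(fitter(X[idx, , drop = FALSE], y[idx]),
                   error = function(e) NULL)
    if (is.null(pf)) { failed <- failed + 1L; next }
    yb <- y[idx]
    pb <- pf(X[idx, , drop = FALSE])
    po <- pf(X)
    boot_app_r2 <- if (stats::sd(pb) == 0) 0 else stats::cor(pb, yb)^2
    orig_r2 <- if (stats::sd(po) == 0) 0 else stats::cor(po, y)^2
    opt_r2 <- c(opt_r2, boot_app_r2 - orig_r2)
    opt_mse <- c(opt_mse, mean((pb - yb)^2) - mean((po - y)^2))
  }
  if (!length(opt_r2))
    stop("all bootstrap replicates failed", call. = FALSE)
  list(apparent_r2 = app_r2, apparent_mse = app_mse,
       optimism_r2 = mean(opt_r2), optimism_mse = mean(opt_mse),
       corrected_r2 = app_r2 - mean(opt_r2),
       corrected_mse = app_mse - mean(opt_mse),
       B = B, failed = failed, seed = seed)
}

#' Full model-comparison report
#'
#' Juxtaposes the mixture and linear models on the four comparison axes:
#' goodness-of-fit (calibration r2, BIC and relative likelihood),
#' discrimination (paired Spearman permutation test), prediction accuracy
#' (MSE pair and relative reduction), and error normality (Q-Q deviation).
#'
#' @param mix_fit A `mixture_fit` (with responsibilities).
#' @param lin_fit A `linear_fit`.
#' @param X Design matrix with intercept.
#' @param y Outcome vector.
#' @param mix_pred Predictions of the mixture model; defaults to
#'   responsibility-weighted in-sample predictions.  For an honest
#'   prediction comparison pass outcome-blind predictions
#'   ([predict_membership()] composed with [predict_weighted()]), as the
#'   pipeline does.
#' @param n_perm Permutations for the Spearman test.
#' @param seed Integer seed.
#' @return List of class `evaluation_report`.
#' @export
evaluate_models <- function(mix_fit, lin_fit, X, y,
                            mix_pred = NULL, n_perm = 10000L, seed = 1L) {
  if (is.null(mix_pred))
    mix_pred <- predict_weighted(mix_fit, X, mix_fit$responsibilities)
  lin_pred <- predict.linear_fit(lin_fit, X)
  sp <- spearman_perm_test(mix_pred, lin_pred, y, n_perm = n_perm,
                           seed = derive_seed(seed, "spearman"))
  structure(list(
    r2 = c(mixture = calibration_r2(mix_pred, y),
           linear = calibration_r2(lin_pred, y)),
    bic = c(mixture = mix_fit$bic, linear = lin_fit$bic),
    relative_likelihood = relative_likelihood(mix_fit$bic, lin_fit$bic),
    rho = c(mixture = sp$rho_a, linear = sp$rho_b),
    perm_p = sp$p,
    mse = c(mixture = mean((mix_pred - y)^2),
            linear = mean((lin_pred - y)^2)),
    relative_mse_reduction = relative_mse_reduction(mix_pred, lin_pred, y),
    qq_deviation = c(
      mixture = qq_deviation(mixture_residuals(mix_fit, X, y)),
      linear = qq_deviation((y - lin_pred) / sqrt(lin_fit$sigma2_mle))),
    n_permutations = n_perm,
    permutation_scheme = "paired per-subject model-label swap",
    qq_statistic = "1 - squared Filliben probability-plot correlation",
    seed = seed
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("model comparison (mixture vs linear)\n")
  cat(sprintf("  calibration r2 : %.4f vs %.4f\n", x$r2[1], x$r2[2]))
  cat(sprintf("  BIC            : %.2f vs %.2f (relative likelihood %s)\n",
              x$bic[1], x$bic[2],
              if (isTRUE(attr(x$relative_likelihood, "log_scale")))
                sprintf("exp(%.1f)", x$relative_likelihood)
              else format(x$relative_likelihood, digits = 4)))
  cat(sprintf("  Spearman rho   : %.4f vs %.4f (permutation p = %.4g)\n",
              x$rho[1], x$rho[2], x$perm_p))
  cat(sprintf("  MSE            : %.5f vs %.5f (relative reduction %.1f%%)\n",
              x$mse[1], x$mse[2], 100 * x$relative_mse_reduction))
  cat(sprintf("  Q-Q deviation  : %.5f vs %.5f\n",
              x$qq_deviation[1], x$qq_deviation[2]))
  invisible(x)
}
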