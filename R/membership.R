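# Outcome-blind subpopulation membership classifier.
#
# After the mixture is fit, a margin-based classifier learns to predict each
# subject's subpopulation from covariates alone (never the observed outcome),
# so that mixture predictions can be formed for new subjects whose outcome is
# unknown.

#' Train the subpopulation membership classifier
#'
#' Trains a support vector machine (RBF kernel, Platt-type probability
#' calibration via libsvm's internal cross-validation) on hard labels
#' `argmax_k r_ik` taken from a converged mixture fit.  Features are
#' standardized to zero mean / unit variance; the outcome column is never
#' seen.
#'
#' @param X Covariate matrix (no outcome, no intercept column needed).
#' @param responsibilities n x K responsibility matrix from a converged
#'   [fit_mixture()].
#' @param kernel,cost SVM kernel and cost; defaults `"radial"`, 1.
#' @param seed Integer seed (probability calibration uses random folds).
#' @return An object of class `membership_model`.
#' @export
train_membership <- function(X, responsibilities, kernel = "radial",
                             cost = 1, seed = 1L) {
  X <- as.matrix(X)
  responsibilities <- as.matrix(responsibilities)
  if (nrow(X) != nrow(responsibilities))
    stop("`X` and `responsibilities` must align", call. = FALSE)
  labels <- max.col(responsibilities, ties.method = "first")
  K <- ncol(responsibilities)
  if (length(unique(labels)) < 2L)
    stop("membership training refused: all subjects map to one component ",
         "(degenerate mixture); a classifier cannot be calibrated",
         call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  set.seed(seed)
  svm_fit <- e1071::svm(x = Xs, y = factor(labels, levels = seq_len(K)),
                        kernel = kernel, cost = cost, probability = TRUE,
                        scale = FALSE)
  structure(list(svm = svm_fit, center = ctr, scale = scl,
                 features = colnames(X), K = K,
                 label_rule = "argmax responsibility", seed = seed,
                 schema_version = 1L),
            class = "membership_model")
}

#' Predict subpopulation membership probabilities
#'
#' @param model A `membership_model`.
#' @param X Covariate matrix with the training feature columns.
#' @return n x K matrix of calibrated membership probabilities (simplex
#'   rows, columns in mixture component order), composable with
#'   [predict_weighted()].
#' @export
predict_membership <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features)) {
    if (!all(model$features %in% colnames(X)))
      stop("feature columns missing: ",
           paste(setdiff(model$features, colnames(X)), collapse = ", "),
           call. = FALSE)
    X <- X[, model$features, drop = FALSE]
  }
  Xs <- scale(X, center = model$center, scale = model$scale)
  pred <- stats::predict(model$svm, Xs, probability = TRUE)
  pr <- attr(pred, "probabilities")
  # libsvm orders probability columns by training-label appearance; restore
  # component order 1..K
  pr <- pr[, as.character(seq_len(model$K)), drop = FALSE]
  pr <- pr / rowSums(pr)
  colnames(pr) <- paste0("p_class", seq_len(model$K))
  unname_rows(pr)
}

unname_rows <- function(m) { rownames(m) <- NULL; m }
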