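# End-to-end orchestration: simulate (or load) a cohort, fit both models,
# train the outcome-blind classifier, evaluate, and run the power comparison,
# writing every stage artifact as diffable JSON/CSV under one run directory.

#' Build a run configuration
#'
#' All stage seeds are derived deterministically from the master seed and
#' the stage name, so adding a stage never perturbs earlier stages'
#' randomness and a re-run with the same configuration is byte-identical.
#'
#' @param n Cohort size to simulate (ignored when `cohort_path` is given).
#' @param cohort_path Optional CSV path of an existing cohort.
#' @param K Number of mixture components.
#' @param n_restarts,max_iter,tol EM settings.
#' @param n_perm Permutations for the Spearman test.
#' @param b_validate Bootstrap-validation replicates (0 disables).
#' @param b_power Power-analysis bootstrap datasets (0 disables).
#' @param alpha Significance level for power.
#' @param mixture_rule Mixture significance rule for power.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n = 614L, cohort_path = NULL, K = 2L,
                       n_restarts = 20L, max_iter = 1000L, tol = 1e-8,
                       n_perm = 10000L, b_validate = 0L, b_power = 0L,
                       alpha = 0.05, mixture_rule = "either", seed = 1L) {
  structure(list(n = as.integer(n), cohort_path = cohort_path,
                 K = as.integer(K), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_perm = as.integer(n_perm),
                 b_validate = as.integer(b_validate),
                 b_power = as.integer(b_power), alpha = alpha,
                 mixture_rule = mixture_rule, seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj[!vapply(obj, is.null, NA)])
}

#' Run the full linear-versus-mixture comparison
#'
#' Simulates (or loads) the cohort, fits the linear baseline and the
#' K-component mixture, trains the outcome-blind membership classifier,
#' evaluates both models on all comparison axes, optionally runs
#' optimism-corrected bootstrap validation and the parametric-bootstrap
#' power comparison, and writes every artifact to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).  `NULL` skips all
#'   file output and returns the results only.
#' @return Invisible list with `cohort`, `lin_fit`, `mix_fit`, `membership`,
#'   `evaluation`, `validation`, `power`, `summary`.
#' @export
run_full_comparison <- function(config = run_config(), out_dir = NULL) {
  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort_csv(config$cohort_path)
  } else {
    simulate_cohort(config$n, seed = derive_seed(config$seed, "cohort"))
  }
  X <- design_matrix(cohort)
  y <- cohort$dscr_48h

  lin_fit <- fit_ols(X, y)
  ctrl <- mixture_control(n_restarts = config$n_restarts,
                          max_iter = config$max_iter, tol = config$tol,
                          seed = derive_seed(config$seed, "em"))
  mix_fit <- fit_mixture(X, y, K = config$K, control = ctrl)
  if (!mix_fit$degenerate && config$K > 1L)
    mix_fit <- component_inference(mix_fit, X, y)

  membership <- NULL
  if (!mix_fit$degenerate && config$K > 1L)
    membership <- train_membership(model_scale_matrix(cohort),
                                   mix_fit$responsibilities,
                                   seed = derive_seed(config$seed, "svm"))

  # predictions for the discrimination/accuracy axes come from the
  # outcome-blind classifier route (responsibilities condition on the
  # observed outcome, so they are not predictions)
  mix_pred <- NULL
  if (!is.null(membership))
    mix_pred <- predict_weighted(mix_fit, X,
                                 predict_membership(membership,
                                                    model_scale_matrix(cohort)))
  evaluation <- evaluate_models(mix_fit, lin_fit, X, y,
                                mix_pred = mix_pred,
                                n_perm = config$n_perm,
                                seed = derive_seed(config$seed, "eval"))

  validation <- NULL
  if (config$b_validate > 0L) {
    ols_fitter <- function(Xb, yb) {
      f <- fit_ols(Xb, yb)
      function(Xn) predict.linear_fit(f, Xn)
    }
    validation <- bootstrap_validate(X, y, ols_fitter, B = config$b_validate,
                                     seed = derive_seed(config$seed, "boot"))
  }

  power <- NULL
  if (config$b_power > 0L && !mix_fit$degenerate && config$K > 1L) {
    power <- power_comparison(
      mix_fit, lin_fit, X, B = config$b_power, alpha = config$alpha,
      mixture_rule = config$mixture_rule,
      seed = derive_seed(config$seed, "power"),
      control = mixture_control(max_iter = 500L))
  }

  summary <- list(
    n = nrow(cohort), K = config$K,
    pi = mix_fit$pi,
    minority_share = mean(mix_fit$responsibilities[, 1] > 0.5),
    bic = evaluation$bic,
    relative_likelihood = as.numeric(evaluation$relative_likelihood),
    relative_likelihood_log_scale =
      isTRUE(attr(evaluation$relative_likelihood, "log_scale")),
    r2 = evaluation$r2, rho = evaluation$rho, perm_p = evaluation$perm_p,
    mse = evaluation$mse,
    relative_mse_reduction = evaluation$relative_mse_reduction,
    qq_deviation = evaluation$qq_deviation,
    power = if (!is.null(power))
      list(gain_median = power$gain_median, gain_range = power$gain_range,
           wins = power$wins, n_comparisons = power$n_comparisons,
           sign_p = power$sign_p),
    seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_fit_json(lin_fit, file.path(out_dir, "fit_linear.json"))
    write_fit_json(mix_fit, file.path(out_dir, "fit_mixture.json"))
    utils::write.csv(
      data.frame(subject_id = cohort$subject_id,
                 round(mix_fit$responsibilities, 10)),
      file.path(out_dir, "responsibilities.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(evaluation),
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
    if (!is.null(validation))
      jsonlite::write_json(validation, file.path(out_dir, "validation.json"),
                           auto_unbox = TRUE, digits = 12, pretty = TRUE)
    if (!is.null(power))
      jsonlite::write_json(unclass(power), file.path(out_dir, "power.json"),
                           auto_unbox = TRUE, digits = 12, na = "null",
                           pretty = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 12, na = "null",
                         pretty = TRUE)
    write_run_config(config, file.path(out_dir, "config.json"))
  }

  invisible(list(cohort = cohort, lin_fit = lin_fit, mix_fit = mix_fit,
                 membership = membership, evaluation = evaluation,
                 validation = validation, power = power, summary = summary))
}
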