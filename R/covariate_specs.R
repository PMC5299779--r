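# Covariate marginal specifications for the synthetic cardiac-surgery cohort.
#
# Continuous covariates are summarized in the source cohort by the median and
# the 10th/90th percentiles only, so each one is modeled with a two-parameter
# family (normal on the raw or the log scale, optionally truncated, optionally
# with a point mass at zero) whose parameters are the least-squares fit of the
# family's quantile function to those three printed quantiles.

#' Construct a covariate marginal specification
#'
#' @param name Column name in the cohort table.
#' @param family One of `"truncnorm"` (normal, truncated below), `"lognormal"`,
#'   `"bernoulli"`, `"zero-inflated-lognormal"`.
#' @param location,scale Family parameters: mean/sd for `"truncnorm"`,
#'   meanlog/sdlog for the lognormal families, prevalence in `location` for
#'   `"bernoulli"`.
#' @param zero_mass Probability of an exact zero (zero-inflated family only).
#' @param lower Lower physical bound for `"truncnorm"` (rejection bound).
#' @param unit Measurement unit string (documentation only).
#' @param model_scale_divisor Positive divisor taking the raw clinical unit to
#'   the per-unit scale on which regression coefficients are expressed
#'   (e.g. 10 for "per 10 years").
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, family, location, scale = NA_real_,
                           zero_mass = 0, lower = -Inf, unit = "",
                           model_scale_divisor = 1) {
  family <- match.arg(family, c("truncnorm", "lognormal", "bernoulli",
                                "zero-inflated-lognormal"))
  if (!is.finite(zero_mass) || zero_mass < 0 || zero_mass > 1)
    stop(sprintf("covariate '%s': zero_mass must be in [0,1]", name),
         call. = FALSE)
  if (family != "bernoulli" && (!is.finite(scale) || scale <= 0))
    stop(sprintf("covariate '%s': scale must be positive", name),
         call. = FALSE)
  if (family == "bernoulli" && (location < 0 || location > 1))
    stop(sprintf("covariate '%s': prevalence must be in [0,1]", name),
         call. = FALSE)
  if (!is.finite(model_scale_divisor) || model_scale_divisor <= 0)
    stop(sprintf("covariate '%s': model_scale_divisor must be positive", name),
         call. = FALSE)
  structure(list(name = name, family = family, location = location,
                 scale = scale, zero_mass = zero_mass, lower = lower,
                 unit = unit, model_scale_divisor = model_scale_divisor),
            class = "covariate_spec")
}

# Least-squares fit of a normal quantile function q_p = mu + sd * z_p to
# target quantiles; closed form (linear regression of targets on z).
fit_normal_quantiles <- function(probs, targets) {
  z <- stats::qnorm(probs)
  sl <- stats::cov(z, targets) / stats::var(z)
  list(mean = mean(targets) - sl * mean(z), sd = sl)
}

fit_lognormal_quantiles <- function(probs, targets) {
  f <- fit_normal_quantiles(probs, log(targets))
  list(meanlog = f$mean, sdlog = f$sd)
}

# Map overall quantile targets of a zero-inflated variable to quantiles of
# its nonzero part: P(X <= q) = zero_mass + (1 - zero_mass) * F_nz(q).
zero_inflated_nonzero_probs <- function(probs, zero_mass) {
  (probs - zero_mass) / (1 - zero_mass)
}

#' Default covariate specifications for the synthetic cohort
#'
#' Returns marginal specifications for the 15 sampled risk-factor covariates
#' (the creatinine-by-age interaction and eGFR are computed, not sampled) plus
#' the auxiliary demographic indicators (`female`, `black`) needed by the
#' CKD-EPI link.  Continuous families are calibrated to the reference cohort's
#' median (10th, 90th) summaries; the cardiopulmonary-bypass, aortic-clamp and
#' hydroxyethyl-starch variables carry a point mass at zero matching the
#' reported usage rates (70.7%, 47.3%, 59/615).
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  q3 <- c(0.1, 0.5, 0.9)

  age <- fit_normal_quantiles(q3, c(50, 67, 81))
  bmi <- fit_lognormal_quantiles(q3, c(22.5, 27.7, 36.9))
  scr <- fit_lognormal_quantiles(q3, c(0.74, 1.01, 1.60))
  hct <- fit_normal_quantiles(q3, c(25, 34, 43))
  uop <- fit_lognormal_quantiles(q3, c(0.175, 0.430, 0.946))
  lac <- fit_lognormal_quantiles(q3, c(0.9, 1.7, 3.8))
  sur <- fit_lognormal_quantiles(q3, c(3.6, 5.1, 7.8))

  # bypass: 70.7% of surgeries used it; nonzero part fit to the overall
  # 50th/90th targets mapped through the zero mass (two quantiles, exact fit)
  cpb_zero <- 1 - 0.707
  cpb_p <- zero_inflated_nonzero_probs(c(0.5, 0.9), cpb_zero)
  cpb <- fit_lognormal_quantiles(cpb_p, c(110.0, 211.6))

  # cross clamp: used in 47.3%; the overall median is 0, leaving one
  # informative quantile (q90).  Shape fixed at sdlog 0.5 (typical clamp-time
  # dispersion), location solved from the q90 target.
  axc_zero <- 1 - 0.473
  axc_p90 <- zero_inflated_nonzero_probs(0.9, axc_zero)
  axc_meanlog <- log(139.6) - stats::qnorm(axc_p90) * 0.5

  list(
    age_yr = covariate_spec("age_yr", "truncnorm", age$mean, age$sd,
                            lower = 18, unit = "years",
                            model_scale_divisor = 10),
    bmi = covariate_spec("bmi", "lognormal", bmi$meanlog, bmi$sdlog,
                         unit = "kg/m2", model_scale_divisor = 5),
    htn = covariate_spec("htn", "bernoulli", 0.885, unit = "0/1"),
    dm = covariate_spec("dm", "bernoulli", 0.328, unit = "0/1"),
    pulse_pressure_mmhg = covariate_spec("pulse_pressure_mmhg", "truncnorm",
                                         60, 15, lower = 20, unit = "mmHg",
                                         model_scale_divisor = 10),
    scr_baseline = covariate_spec("scr_baseline", "lognormal", scr$meanlog,
                                  scr$sdlog, unit = "mg/dL"),
    hct_pct = covariate_spec("hct_pct", "truncnorm", hct$mean, hct$sd,
                             lower = 10, unit = "%"),
    cpb_min = covariate_spec("cpb_min", "zero-inflated-lognormal",
                             cpb$meanlog, cpb$sdlog, zero_mass = cpb_zero,
                             unit = "min", model_scale_divisor = 60),
    axc_min = covariate_spec("axc_min", "zero-inflated-lognormal",
                             axc_meanlog, 0.5, zero_mass = axc_zero,
                             unit = "min", model_scale_divisor = 60),
    hes_l = covariate_spec("hes_l", "zero-inflated-lognormal",
                           log(0.5), 0.5, zero_mass = 1 - 59 / 615,
                           unit = "L"),
    uop_l = covariate_spec("uop_l", "lognormal", uop$meanlog, uop$sdlog,
                           unit = "L"),
    map_adj_mmhg = covariate_spec("map_adj_mmhg", "truncnorm", 0, 8,
                                  unit = "mmHg", model_scale_divisor = 10),
    lactate_max = covariate_spec("lactate_max", "lognormal", lac$meanlog,
                                 lac$sdlog, unit = "mmol/L"),
    surgery_h = covariate_spec("surgery_h", "lognormal", sur$meanlog,
                               sur$sdlog, unit = "h"),
    female = covariate_spec("female", "bernoulli", 0.306, unit = "0/1"),
    black = covariate_spec("black", "bernoulli", 0.042, unit = "0/1")
  )
}

# one draw of n values from a single covariate_spec
sample_one_covariate <- function(spec, n) {
  x <- switch(spec$family,
    truncnorm = {
      v <- stats::rnorm(n, spec$location, spec$scale)
      while (any(bad <- v <= spec$lower))
        v[bad] <- stats::rnorm(sum(bad), spec$location, spec$scale)
      v
    },
    lognormal = stats::rlnorm(n, spec$location, spec$scale),
    bernoulli = stats::rbinom(n, 1L, spec$location),
    `zero-inflated-lognormal` = {
      nz <- stats::rbinom(n, 1L, 1 - spec$zero_mass)
      v <- numeric(n)
      v[nz == 1L] <- stats::rlnorm(sum(nz), spec$location, spec$scale)
      v
    })
  x
}

#' Covariate model-scale divisors
#'
#' The per-unit scale on which all regression coefficients are expressed
#' (e.g. age per 10 years, bypass time per hour).  Cohort tables always store
#' raw clinical units; model code divides by these immediately before fitting.
#'
#' @return Named numeric vector over the 16 model covariate terms, in the
#'   canonical term order.
#' @export
model_scale_divisors <- function() {
  c(age_yr = 10, bmi = 5, htn = 1, dm = 1, pulse_pressure_mmhg = 10,
    scr_baseline = 1, scr_age_interaction = 1, egfr = 30, hct_pct = 1,
    cpb_min = 60, axc_min = 60, hes_l = 1, uop_l = 1, map_adj_mmhg = 10,
    lactate_max = 1, surgery_h = 1)
}

#' Canonical model covariate term order
#' @return Character vector of the 16 covariate column names.
#' @export
covariate_terms <- function() names(model_scale_divisors())
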