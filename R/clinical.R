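#' Estimate glomerular filtration rate with the CKD-EPI creatinine equation
#'
#' Computes the 2009 CKD-EPI creatinine-based estimated glomerular filtration
#' rate (eGFR).  The equation is a piecewise power law in serum creatinine
#' with sex-specific knot (0.7 mg/dL female, 0.9 mg/dL male) and exponents,
#' an exponential age decline (0.993 per year) and a race multiplier.
#'
#' @param scr Serum creatinine, mg/dL.  Must be positive.
#' @param age Age in years.  Must be positive.
#' @param female Logical (or 0/1): subject is female.
#' @param black Logical (or 0/1): subject is African American.
#' @return eGFR in mL/min/1.73 m^2.  Vectorized over all arguments.
#' @examples
#' compute_ckd_epi_egfr(0.9, 50, female = FALSE, black = FALSE) # ~99.2
#' compute_ckd_epi_egfr(0.7, 40, female = TRUE, black = FALSE)  # ~108.7
#' @export
compute_ckd_epi_egfr <- function(scr, age, female, black = FALSE) {
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("`scr` must be positive", call. = FALSE)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("`age` must be positive", call. = FALSE)
  female <- as.logical(female)
  black <- as.logical(black)
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- ifelse(female, 144, 141)
  r <- scr / kappa
  base * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(black, 1.159, 1)
}

#' Stage acute kidney injury by the KDIGO serum-creatinine criteria
#'
#' Assigns the highest applicable KDIGO stage from baseline creatinine, the
#' maximum creatinine within 48 h, the maximum within 7 days, and receipt of
#' renal replacement therapy (RRT).  Stage 1 requires a >= 0.3 mg/dL rise
#' within 48 h or a >= 1.5-fold rise within 7 days; stage 2 a >= 2-fold rise;
#' stage 3 a >= 3-fold rise, a 7-day maximum >= 4.0 mg/dL, or RRT.  Urine
#' output criteria are not evaluated (no urine time series in the data model).
#'
#' @param baseline_scr Baseline serum creatinine, mg/dL (> 0).
#' @param max_scr_48h Maximum serum creatinine over the first 48 h, mg/dL.
#' @param max_scr_7d Maximum serum creatinine over the first 7 days, mg/dL.
#' @param rrt Logical: renal replacement therapy received.
#' @return Integer stage in 0:3 (0 = no AKI).  Vectorized.
#' @examples
#' classify_kdigo(1.0, 1.3, 1.3, FALSE) # stage 1 (0.3 mg/dL rise in 48 h)
#' classify_kdigo(1.0, 1.2, 3.1, FALSE) # stage 3 (>= 3x baseline)
#' @export
classify_kdigo <- function(baseline_scr, max_scr_48h, max_scr_7d, rrt = FALSE) {
  if (any(!is.finite(baseline_scr)) || any(baseline_scr <= 0))
    stop("`baseline_scr` must be positive", call. = FALSE)
  if (any(!is.finite(max_scr_48h)) || any(max_scr_48h <= 0) ||
      any(!is.finite(max_scr_7d)) || any(max_scr_7d <= 0))
    stop("creatinine values must be positive", call. = FALSE)
  n <- max(length(baseline_scr), length(max_scr_48h), length(max_scr_7d),
           length(rrt))
  b <- rep_len(baseline_scr, n)
  m48 <- rep_len(max_scr_48h, n)
  m7 <- rep_len(max_scr_7d, n)
  rrt <- rep_len(as.logical(rrt), n)
  stage <- integer(n)
  stage[(m48 - b >= 0.3) | (m7 >= 1.5 * b)] <- 1L
  stage[m7 >= 2.0 * b] <- 2L
  stage[(m7 >= 3.0 * b) | (m7 >= 4.0) | rrt] <- 3L
  stage
}
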