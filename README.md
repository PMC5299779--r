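# akimix

Latent-variable mixture modeling of postoperative serum-creatinine change.

## The problem

Acute kidney injury (AKI) after cardiac surgery is diagnosed from the rise
in serum creatinine, and risk-factor analyses usually regress the maximum
48-h creatinine change (ΔSCr, mg/dL) on established clinical covariates.
Unmeasured factors — renal functional reserve, creatinine production,
hemodilution — make such cohorts heterogeneous: a single linear model
averages over distinct patient subpopulations, attenuating coefficients and
losing power. `akimix` is for biostatisticians and clinical researchers who
want to account for that heterogeneity with a latent-variable mixture of
regressions and to quantify what it buys over the linear baseline.

## The model

ΔSCr is modeled as a two-component Gaussian mixture of linear regressions

    y_i | x_i  ~  Σ_k π_k · N(x_i'β_k, σ_k²),    k = 1, 2,

fit by EM: membership probabilities are randomly initialized per subject
(flat Dirichlet), then refined by alternating posterior (E) and
responsibility-weighted least-squares (M) steps to convergence, with
multiple restarts. Component 1 is the minority subpopulation in which risk
factors correlate strongly with ΔSCr. Around the core fit the package
provides:

* `fit_ols()` — the OLS baseline, exactly the K = 1 special case, with a
  comparable BIC;
* `train_membership()` / `predict_membership()` — an outcome-blind SVM that
  predicts subpopulation membership from covariates only, enabling honest
  mixture prediction via `predict_weighted()`;
* `evaluate_models()` — calibration r², BIC relative likelihood
  exp(ΔBIC/2), a paired Spearman permutation test of discrimination,
  relative MSE reduction, Filliben Q-Q deviation of residuals, and
  `bootstrap_validate()` for optimism correction;
* `power_comparison()` — parametric-bootstrap per-covariate power for both
  models, relative gains, and an exact sign test;
* `simulate_cohort()` — a synthetic cardiac-surgery cohort with published
  covariate marginals (zero-inflated bypass/clamp/starch variables, CKD-EPI
  eGFR link), a 13% latent minority, and per-unit-scale component
  coefficients as generative truth;
* clinical utilities `compute_ckd_epi_egfr()` and `classify_kdigo()`.

## Worked example

```r
library(akimix)

cohort <- simulate_cohort(614, generative_model(), seed = 1)
X <- design_matrix(cohort)          # intercept + 16 per-unit-scale terms
y <- cohort$dscr_48h

lin <- fit_ols(X, y)
mix <- component_inference(
  fit_mixture(X, y, K = 2, control = mixture_control(seed = 1)), X, y)
mix
#> 2-component mixture of linear regressions (n = 614)
#>   mixing weights: 0.111, 0.889
#>   loglik 378.763, BIC -519.986, 43 iterations, converged: TRUE

mm <- train_membership(model_scale_matrix(cohort), mix$responsibilities)
blind <- predict_weighted(mix, X,
                          predict_membership(mm, model_scale_matrix(cohort)))
evaluate_models(mix, lin, X, y, mix_pred = blind)
#> model comparison (mixture vs linear)
#>   calibration r2 : 0.2458 vs 0.2805
#>   BIC            : -519.99 vs -272.38 (relative likelihood 5.841e+53)
#>   Spearman rho   : 0.5655 vs 0.5692 (permutation p = 0.6844)
#>   MSE            : 0.03274 vs 0.03113 (relative reduction -5.2%)
#>   Q-Q deviation  : 0.00523 vs 0.13854

power_comparison(mix, lin, X, B = 500, seed = 1)
#> parametric-bootstrap power comparison (B = 500, alpha = 0.05)
#>   mixture wins 13 of 13 covariates (sign test p = 0.000244)
#>   relative power gain: median 820% (range 0 to 18900%)
#>   1 replicate fit(s) failed and were dropped
```

Reading the numbers: the mixture recovers an ~11% minority subpopulation
and fits this cohort decisively better (ΔBIC ≈ 248, i.e. a relative
likelihood of ~6×10⁵³; near-zero Q-Q deviation means its errors are far
closer to normal), and it wins every informative per-covariate power
comparison. The outcome-blind *prediction* axes are the hard part: at this
seed the SVM extracts too little class signal from covariates, so blind
mixture predictions merely track OLS (−5.2% MSE, permutation p = 0.68).
Fit and power advantages come from the mixture itself; prediction
advantages require covariates that identify the latent class — see the
vignette for the two regimes. A subpopulation-1 coefficient after
inference: `mix$components[[1]]$beta[["bmi"]]` → 0.101 per 5 kg/m²
(p ≈ 4.5e-4).

One-call pipeline writing all artifacts (cohort CSV, fit JSONs,
evaluation, power, summary):

```r
run_full_comparison(run_config(n = 614, b_power = 500, seed = 1), "run1")
```

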