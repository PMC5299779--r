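# Synthetic cohort generator: covariate marginals, latent structure, outcome.

test_that("sampled covariate marginals track the reference cohort summaries", {
  cohort <- sample_covariates(n = 10000, seed = 101)

  targets <- list(
    age_yr = c(50, 67, 81),
    bmi = c(22.5, 27.7, 36.9),
    scr_baseline = c(0.74, 1.01, 1.60),
    hct_pct = c(25, 34, 43),
    uop_l = c(0.175, 0.430, 0.946),
    lactate_max = c(0.9, 1.7, 3.8),
    surgery_h = c(3.6, 5.1, 7.8))
  for (nm in names(targets)) {
    q <- unname(quantile(cohort[[nm]], c(0.1, 0.5, 0.9)))
    # two-parameter families fit to three printed quantiles: allow the
    # least-squares fitting slack plus Monte-Carlo error
    expect_lt(max(abs(q - targets[[nm]]) /
                    pmax(abs(targets[[nm]]), 0.5)), 0.08,
              label = sprintf("relative quantile error for %s", nm))
  }
  # age percentiles within +-2 years of the printed summary
  expect_lt(max(abs(quantile(cohort$age_yr, c(0.1, 0.5, 0.9)) -
                      c(50, 67, 81))), 2)

  # binary prevalences
  expect_lt(abs(mean(cohort$htn) - 0.885), 0.02)
  expect_lt(abs(mean(cohort$dm) - 0.328), 0.02)
  expect_lt(abs(mean(cohort$female) - 0.306), 0.02)

  # zero-inflation: starch given to 59/615, bypass in 70.7%, clamp in 47.3%
  expect_lt(abs(mean(cohort$hes_l == 0) - (1 - 59 / 615)), 0.02)
  expect_lt(abs(mean(cohort$cpb_min == 0) - (1 - 0.707)), 0.02)
  expect_lt(abs(mean(cohort$axc_min == 0) - (1 - 0.473)), 0.02)
  # bypass overall median / q90 match the printed summaries
  expect_equal(unname(median(cohort$cpb_min)), 110, tolerance = 0.06)
  expect_equal(unname(quantile(cohort$cpb_min, 0.9)), 211.6,
               tolerance = 0.06, ignore_attr = TRUE)
})

test_that("cohort tables respect physical bounds and derived-column identities", {
  cohort <- sample_covariates(n = 2000, seed = 7)
  expect_true(all(cohort$age_yr > 18))
  expect_true(all(cohort$bmi > 0))
  expect_true(all(cohort$hct_pct > 10 & cohort$hct_pct < 60))
  expect_true(all(cohort$cpb_min >= 0 & cohort$axc_min >= 0 &
                    cohort$hes_l >= 0 & cohort$uop_l >= 0))
  expect_true(all(cohort$htn %in% 0:1 & cohort$dm %in% 0:1))
  expect_equal(cohort$scr_age_interaction,
               cohort$scr_baseline * cohort$age_yr)
  expect_equal(cohort$egfr,
               compute_ckd_epi_egfr(cohort$scr_baseline, cohort$age_yr,
                                    cohort$female, cohort$black))
})

test_that("covariate sampling is reproducible and validates its inputs", {
  expect_identical(sample_covariates(n = 1, seed = 3),
                   sample_covariates(n = 1, seed = 3))
  expect_identical(sample_covariates(n = 50, seed = 9),
                   sample_covariates(n = 50, seed = 9))
  specs <- default_covariate_specs()
  specs$bmi <- NULL
  expect_error(sample_covariates(specs, n = 5), "bmi")
  expect_error(covariate_spec("x", "lognormal", 1, -2), "scale")
  expect_error(covariate_spec("x", "zero-inflated-lognormal", 1, 1,
                              zero_mass = 1.4), "zero_mass")
})

test_that("latent class assignment hits the mixing weight and degenerates cleanly", {
  cohort <- sample_covariates(n = 10000, seed = 21)
  gen0 <- generative_model(pi1 = 0, class_covariate_shift = NULL)
  expect_true(all(assign_latent_classes(cohort, gen0, seed = 1) == 2L))

  gen <- generative_model(pi1 = 0.13, class_covariate_shift = NULL)
  labels <- assign_latent_classes(cohort, gen, seed = 22)
  expect_lt(abs(mean(labels == 1L) - 0.13), 0.01)
})

test_that("minority-class covariate shifts act as constructed", {
  cohort <- sample_covariates(n = 6000, seed = 31)
  gen <- generative_model(pi1 = 0.5,
                          class_covariate_shift = c(age_yr = 10))
  labels <- assign_latent_classes(cohort, gen, seed = 32)
  set.seed(33)
  shifted <- apply_class_shifts(cohort, labels, gen)
  gap <- mean(shifted$age_yr[labels == 1L]) -
    mean(shifted$age_yr[labels == 2L])
  expect_equal(gap, 10, tolerance = 0.1)
  # derived columns refreshed: shifted rows have recomputed interaction
  expect_equal(shifted$scr_age_interaction,
               shifted$scr_baseline * shifted$age_yr)

  # default shifts: class 1 older, higher creatinine, lower eGFR
  gen_d <- generative_model(pi1 = 0.3)
  lab_d <- assign_latent_classes(cohort, gen_d, seed = 34)
  set.seed(35)
  sh <- apply_class_shifts(cohort, lab_d, gen_d)
  expect_gt(mean(sh$age_yr[lab_d == 1]), mean(sh$age_yr[lab_d == 2]) + 5)
  expect_lt(mean(sh$egfr[lab_d == 1]), mean(sh$egfr[lab_d == 2]) - 8)
  expect_gt(mean(sh$htn[lab_d == 1]), mean(sh$htn[lab_d == 2]))
})

test_that("outcome generation applies component models on the per-unit scale", {
  # noise-free, all covariates zero: outcome is the component intercept
  zero <- as.data.frame(setNames(as.list(numeric(17)),
                                 c(covariate_terms(), "subject_id")))
  gen <- generative_model(sigma1 = 0, sigma2 = 0,
                          class_covariate_shift = NULL)
  expect_equal(generate_outcome(zero, 2L, gen, seed = 1), gen$intercept2)
  expect_equal(generate_outcome(zero, 1L, gen, seed = 1), gen$intercept1)

  # a 5 kg/m^2 BMI difference moves the subpopulation-1 outcome by the
  # generating per-5-unit coefficient, 0.107
  pair <- rbind(zero, zero)
  pair$bmi <- c(25, 30)
  y <- generate_outcome(pair, c(1L, 1L), gen, seed = 1)
  expect_equal(y[2] - y[1], 0.107, tolerance = 1e-12)

  # conditional outcome variance matches the component noise model
  one_row <- sample_covariates(n = 1, seed = 41)
  big <- one_row[rep(1, 50000), ]
  gen_n <- generative_model(sigma1 = 0.25, sigma2 = 0.10,
                            class_covariate_shift = NULL)
  y1 <- generate_outcome(big, rep(1L, 50000), gen_n, seed = 42)
  y2 <- generate_outcome(big, rep(2L, 50000), gen_n, seed = 43)
  expect_lt(abs(var(y1) / 0.25^2 - 1), 0.05)
  expect_lt(abs(var(y2) / 0.10^2 - 1), 0.05)

  expect_error(generate_outcome(zero[, -1], 2L, gen), "terms")
})

test_that("equal components collapse to a single linear model distributionally", {
  b <- reference_component_betas()$subpop2
  gen_eq <- generative_model(pi1 = 0.4, beta1 = b, beta2 = b,
                             intercept1 = -0.65, intercept2 = -0.65,
                             sigma1 = 0.1, sigma2 = 0.1,
                             class_covariate_shift = NULL)
  pass <- 0L
  for (rep in 1:10) {
    cohort <- sample_covariates(n = 1500, seed = 500 + rep)
    labels <- assign_latent_classes(cohort, gen_eq, seed = 600 + rep)
    y_mixed <- generate_outcome(cohort, labels, gen_eq, seed = 700 + rep)
    y_single <- generate_outcome(cohort, rep(2L, 1500), gen_eq,
                                 seed = 800 + rep)
    if (suppressWarnings(ks.test(y_mixed, y_single)$p.value) > 0.01)
      pass <- pass + 1L
  }
  expect_gte(pass, 9L)
})

test_that("simulated cohorts are reproducible and round-trip through CSV", {
  c1 <- simulate_cohort(200, seed = 11)
  c2 <- simulate_cohort(200, seed = 11)
  expect_identical(c1, c2)
  expect_false(anyNA(c1$dscr_48h))
  expect_true(all(c1$true_class %in% 1:2))

  path <- tempfile(fileext = ".csv")
  write_cohort_csv(c1, path)
  back <- read_cohort_csv(path)
  expect_equal(back$dscr_48h, c1$dscr_48h, tolerance = 1e-12)
  expect_equal(back$age_yr, c1$age_yr, tolerance = 1e-12)
  expect_error(read_cohort_csv({
    p2 <- tempfile(fileext = ".csv")
    write.csv(c1[, 1:5], p2, row.names = FALSE)
    p2
  }), "required column")
})

test_that("CKD-EPI eGFR matches direct evaluation and is monotone", {
  expect_equal(compute_ckd_epi_egfr(0.9, 50, FALSE, FALSE),
               141 * 0.993^50, tolerance = 1e-12)
  expect_equal(compute_ckd_epi_egfr(0.7, 40, TRUE, FALSE),
               144 * 0.993^40, tolerance = 1e-12)
  # piecewise branches, evaluated from the published equation directly
  expect_equal(compute_ckd_epi_egfr(1.4, 60, FALSE, FALSE),
               141 * (1.4 / 0.9)^(-1.209) * 0.993^60, tolerance = 1e-12)
  expect_equal(compute_ckd_epi_egfr(0.5, 30, TRUE, TRUE),
               144 * (0.5 / 0.7)^(-0.329) * 0.993^30 * 1.159,
               tolerance = 1e-12)
  # strictly decreasing in creatinine and in age
  scr_grid <- seq(0.4, 3, by = 0.1)
  expect_true(all(diff(compute_ckd_epi_egfr(scr_grid, 50, FALSE)) < 0))
  expect_true(all(compute_ckd_epi_egfr(1, 80, TRUE) <
                    compute_ckd_epi_egfr(1, 40, TRUE)))
  expect_error(compute_ckd_epi_egfr(0, 50, FALSE), "positive")
  expect_error(compute_ckd_epi_egfr(1, -2, FALSE), "positive")
})

test_that("KDIGO staging agrees with an independent rule-table oracle", {
  expect_identical(classify_kdigo(1.0, 1.05, 1.1, FALSE), 0L)
  expect_identical(classify_kdigo(1.0, 1.3, 1.3, FALSE), 1L)
  expect_identical(classify_kdigo(1.0, 1.2, 3.1, FALSE), 3L)

  grid <- expand.grid(b = c(0.6, 1.0, 1.4, 2.0),
                      d48 = c(-0.1, 0, 0.25, 0.3, 0.6),
                      mult = c(0.9, 1.2, 1.5, 1.9, 2.0, 2.9, 3.0, 4.5),
                      rrt = c(FALSE, TRUE))
  grid$m48 <- pmax(grid$b + grid$d48, 0.1)
  grid$m7 <- grid$b * grid$mult
  got <- classify_kdigo(grid$b, grid$m48, grid$m7, grid$rrt)
  want <- mapply(oracle_kdigo, grid$b, grid$m48, grid$m7, grid$rrt)
  expect_identical(got, as.integer(want))
  expect_error(classify_kdigo(-1, 1, 1), "positive")
})
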