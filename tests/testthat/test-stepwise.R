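test_that("logistic MLE recovers a single strong effect and satisfies the
           AIC identity", {
  specs <- toy_specs(prevalence = 0.3, beta = log(6.30), names = "Lactate")
  cohort <- generate_cohort(specs, n = 1e5, intercept = qlogis(0.10),
                            seed = 1)
  fit <- fit_logistic(cohort)
  or <- wald_odds_ratios(fit)
  expect_gt(or$odds_ratio, 5.7)
  expect_lt(or$odds_ratio, 7.0)
  expect_true(or$ci_low < 6.30 & 6.30 < or$ci_high)
  # AIC = 2*(params incl. intercept) - 2*logLik, with the log-likelihood
  # recomputed independently from the fitted probabilities
  p_hat <- plogis(fit$intercept + as.matrix(cohort["Lactate"]) %*%
                    fit$coefficients)
  ll <- sum(log(ifelse(cohort$outcome == 1, p_hat, 1 - p_hat)))
  expect_equal(fit$aic, 2 * 2 - 2 * ll, tolerance = 1e-6)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-6)
})

test_that("null predictors give small coefficients and near-null AIC", {
  cohort <- withr::with_seed(2, tibble::tibble(
    A = rbinom(20000, 1, 0.3),
    B = rbinom(20000, 1, 0.1),
    outcome = rbinom(20000, 1, 0.2)
  ))
  fit <- fit_logistic(cohort)
  expect_true(all(abs(fit$coefficients) < 0.2))
  null_aic <- stats::AIC(glm(outcome ~ 1, data = cohort,
                             family = binomial()))
  expect_gt(fit$aic, null_aic - 2)        # can beat null by chance only a bit
  expect_lt(fit$aic, null_aic + 2 * 2 + 1) # at most the parameter penalty
})

test_that("separation and degenerate designs are detected", {
  cohort <- withr::with_seed(3, {
    y <- rbinom(200, 1, 0.4)
    tibble::tibble(Sep = y, Ok = rbinom(200, 1, 0.5), outcome = y)
  })
  fit <- suppressWarnings(fit_logistic(cohort))
  expect_true(fit$separation_flag)
  expect_false(wald_odds_ratios(fit)$reliable[1])
  # constant column dropped with a warning
  cohort2 <- dplyr::mutate(cohort, Const = 0)
  suppressWarnings(
    expect_warning(fit2 <- fit_logistic(cohort2), "constant")
  )
  expect_equal(fit2$dropped, "Const")
  # exact duplicates are a singular design
  cohort3 <- withr::with_seed(4, {
    x <- rbinom(300, 1, 0.4)
    tibble::tibble(A = x, B = x,
                   outcome = rbinom(300, 1, plogis(-1 + x)))
  })
  expect_error(fit_logistic(cohort3), "collinear")
})

test_that("Wald intervals widen monotonically with the standard error", {
  z <- qnorm(0.975)
  widths <- vapply(c(0.05, 0.1, 0.2, 0.4), function(se) {
    exp(0.5 + z * se) - exp(0.5 - z * se)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  # a null coefficient yields OR 1 with a CI spanning 1
  cohort <- withr::with_seed(5, tibble::tibble(
    A = rbinom(5000, 1, 0.5), outcome = rbinom(5000, 1, 0.3)
  ))
  or <- wald_odds_ratios(fit_logistic(cohort))
  expect_lt(or$ci_low, 1)
  expect_gt(or$ci_high, 1)
})

test_that("backward stepwise reproduces the exhaustive single-removal AIC
           oracle on small problems", {
  for (s in 1:4) {
    specs <- toy_specs(
      prevalence = c(0.3, 0.2, 0.4, 0.25, 0.35),
      beta = c(log(4), log(2.5), 0, 0, 0)
    )
    cohort <- generate_cohort(specs, n = 800, intercept = -1.5, seed = s)
    got <- backward_stepwise(cohort, cv = FALSE)
    want <- backward_oracle(cohort)
    expect_setequal(got$retained, want$retained)
    expect_equal(got$trajectory$predictor, want$trajectory$predictor)
    expect_equal(got$trajectory$aic, want$trajectory$aic, tolerance = 1e-6)
    # trajectory AIC is non-increasing
    expect_true(all(diff(got$trajectory$aic) <= 1e-6))
  }
})

test_that("backward stepwise keeps strong effects, drops noise, and
           matches MASS::stepAIC", {
  specs <- toy_specs(prevalence = c(0.3, 0.3), beta = c(log(6), 0),
                     names = c("Strong", "Noise"))
  cohort <- generate_cohort(specs, n = 5000, intercept = -2, seed = 6)
  got <- backward_stepwise(cohort, cv = FALSE)
  expect_true("Strong" %in% got$retained)
  expect_false("Noise" %in% got$retained)

  skip_if_not_installed("MASS")
  full <- glm(outcome ~ Strong + Noise,
              data = dplyr::select(cohort, -subject_id),
              family = binomial())
  ref <- MASS::stepAIC(full, direction = "backward", trace = 0)
  expect_setequal(got$retained,
                  setdiff(names(coef(ref)), "(Intercept)"))
})

test_that("all-noise designs are mostly eliminated", {
  cohort <- withr::with_seed(7, {
    X <- matrix(rbinom(5000 * 6, 1, 0.3), ncol = 6,
                dimnames = list(NULL, paste0("N", 1:6)))
    dplyr::bind_cols(tibble::as_tibble(X),
                     tibble::tibble(outcome = rbinom(5000, 1, 0.25)))
  })
  got <- backward_stepwise(cohort, cv = FALSE)
  expect_lte(length(got$retained), 2)
})

test_that("forward stepwise adds the informative predictor first and agrees
           with backward on well-separated orthogonal designs", {
  specs <- toy_specs(prevalence = c(0.3, 0.3), beta = c(log(6), 0),
                     names = c("Strong", "Noise"))
  cohort <- generate_cohort(specs, n = 5000, intercept = -2, seed = 8)
  fw <- forward_stepwise(cohort, cv = FALSE)
  expect_equal(fw$trajectory$predictor[2], "Strong")
  bw <- backward_stepwise(cohort, cv = FALSE)
  expect_setequal(fw$retained, bw$retained)
})

test_that("cross-validated logistic AUC is calibrated at the extremes and
           deterministic", {
  cohort <- withr::with_seed(9, {
    y <- rbinom(2000, 1, 0.3)
    tibble::tibble(Perfect = y, outcome = y)
  })
  est <- suppressWarnings(
    cv_logistic_auc(cohort, "Perfect", k_folds = 5, seed = 1, n_boot = 300)
  )
  expect_gt(est$auc, 0.99)

  null_cohort <- withr::with_seed(10, tibble::tibble(
    A = rbinom(5000, 1, 0.3), B = rbinom(5000, 1, 0.2),
    outcome = rbinom(5000, 1, 0.25)
  ))
  est0 <- cv_logistic_auc(null_cohort, c("A", "B"), k_folds = 5, seed = 2,
                          n_boot = 300)
  expect_gt(est0$auc, 0.45)
  expect_lt(est0$auc, 0.55)
  expect_identical(
    est0,
    cv_logistic_auc(null_cohort, c("A", "B"), k_folds = 5, seed = 2,
                    n_boot = 300)
  )
})

test_that("stepwise tidiers expose the retained model", {
  specs <- toy_specs(prevalence = c(0.3, 0.25), beta = c(log(4), log(2)))
  cohort <- generate_cohort(specs, n = 2000, intercept = -1.5, seed = 11)
  sw <- backward_stepwise(cohort, k_folds = 5, n_boot = 300, seed = 3)
  td <- tidy(sw)
  expect_true(all(c("term", "odds_ratio", "conf_low") %in% names(td)))
  expect_equal(nrow(td), length(sw$retained))
  gl <- glance(sw)
  expect_equal(gl$direction, "backward")
  expect_equal(gl$cv_auc, sw$cv_auc$auc)
})
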