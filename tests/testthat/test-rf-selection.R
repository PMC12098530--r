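test_that("importance averaging ranks a perfect predictor first and is
           deterministic", {
  cohort <- withr::with_seed(1, {
    y <- rbinom(300, 1, 0.4)
    tibble::tibble(Copy = y, Rand = rbinom(300, 1, 0.5), outcome = y)
  })
  imp <- average_importance(cohort, mtry = 1, n_trees = 100, n_repeats = 3,
                            seed = 5)
  expect_s3_class(imp, "lpp_importance")
  expect_equal(imp$predictor[imp$rank == 1], "Copy")
  expect_equal(sort(imp$rank), 1:2)
  # the unrelated predictor's mean importance sits near its permutation null
  rand <- imp[imp$predictor == "Rand", ]
  expect_lt(abs(rand$mean_importance), 3 * rand$sd_importance + 1e-3)
  expect_identical(
    imp,
    average_importance(cohort, mtry = 1, n_trees = 100, n_repeats = 3,
                       seed = 5)
  )
})

test_that("negative-importance filtering is forced by the definition", {
  tbl <- tibble::tibble(
    predictor = c("A", "B", "C"),
    mean_importance = c(0.02, -0.001, 0.01),
    sd_importance = rep(0.001, 3),
    rank = 1:3
  )
  expect_equal(filter_negative(tbl), c("A", "C"))
  all_neg <- dplyr::mutate(tbl, mean_importance = -abs(mean_importance))
  expect_warning(out <- filter_negative(all_neg), "no predictor")
  expect_length(out, 0)
  all_pos <- dplyr::mutate(tbl, mean_importance = abs(mean_importance))
  expect_equal(filter_negative(all_pos), c("A", "B", "C"))
  # exact zero is non-positive and removed
  zero <- dplyr::mutate(tbl, mean_importance = c(0.02, 0, 0.01))
  expect_equal(filter_negative(zero), c("A", "C"))
})

test_that("out-of-fold forest predictions partition subjects and separate
           a perfect predictor", {
  cohort <- withr::with_seed(2, {
    y <- rbinom(2000, 1, 0.3)
    tibble::tibble(Perfect = y, outcome = y)
  })
  cv <- cv_forest_predictions(cohort, mtry = 1, n_trees = 100, k_folds = 5,
                              seed = 3)
  expect_equal(cv$row_id, 1:2000)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_true(all(tabulate(cv$fold, 5) > 0))
  expect_gt(auc_mann_whitney(cv), 0.95)
  # fold assignment is deterministic in the seed and stratified
  f1 <- make_folds(cohort$outcome, 10, seed = 7)
  expect_identical(f1, make_folds(cohort$outcome, 10, seed = 7))
  pos_per_fold <- tapply(cohort$outcome, f1, mean)
  expect_lt(diff(range(pos_per_fold)), 0.05)
})

test_that("sequential selection finds a small model when signal is
           concentrated in the top ranks", {
  cohort <- signal_noise_cohort(n = 800, n_signal = 3, n_noise = 5,
                                seed = 4)
  imp <- average_importance(cohort, mtry = 2, n_trees = 150, n_repeats = 2,
                            seed = 1)
  expect_setequal(imp$predictor[imp$rank <= 3],
                  c("Sig1", "Sig2", "Sig3"))
  sel <- sequential_selection(cohort, filter_negative(imp), mtry = 2,
                              n_trees = 150, k_folds = 5, n_boot = 300,
                              seed = 2)
  expect_s3_class(sel, "lpp_rf_selection")
  expect_false(is.na(sel$chosen_k))
  expect_lte(sel$chosen_k, 5)
  expect_equal(sel$retained, sel$ranked[seq_len(sel$chosen_k)])
  # nested table covers k_min..|ranked| with CIs bracketing each AUC
  expect_equal(sel$nested$k, seq(3, length(sel$ranked)))
  expect_true(all(sel$nested$ci_low <= sel$nested$auc))
  expect_true(all(sel$nested$ci_high >= sel$nested$auc))
})

test_that("a sub-model on the full candidate set reproduces the full model
           exactly, and degenerate alpha thresholds behave as forced", {
  cohort <- signal_noise_cohort(n = 400, n_signal = 2, n_noise = 2,
                                seed = 6)
  preds <- setdiff(names(cohort), c("subject_id", "outcome"))
  sel <- sequential_selection(cohort, ranked = sort(preds), mtry = 2,
                              n_trees = 60, k_folds = 3, n_boot = 200,
                              seed = 3)
  expect_equal(sel$nested$delong_p[sel$nested$k == 4], 1) # self-comparison
  expect_equal(sel$nested$auc[sel$nested$k == 4], sel$full_auc$auc)
  # alpha = 0: every sub-model is "not significantly different" -> k_min
  sel0 <- sequential_selection(cohort, ranked = sort(preds), mtry = 2,
                               n_trees = 60, k_folds = 3, alpha = 0,
                               n_boot = 200, seed = 3)
  expect_equal(sel0$chosen_k, 3)
  # alpha = 1: only an exact duplicate of the full model (p = 1) qualifies
  sel1 <- sequential_selection(cohort, ranked = sort(preds), mtry = 2,
                               n_trees = 60, k_folds = 3, alpha = 1,
                               n_boot = 200, seed = 3)
  expect_equal(sel1$chosen_k, 4)
})

test_that("mtry sweep returns one importance table per value and broadly
           consistent rankings", {
  specs <- default_predictor_specs()
  cohort <- generate_cohort(specs, n = 800, seed = 12)
  imp3 <- average_importance(cohort, mtry = 3, n_trees = 150, n_repeats = 2,
                             seed = 31)
  imp6 <- average_importance(cohort, mtry = 6, n_trees = 150, n_repeats = 2,
                             seed = 32)
  merged <- dplyr::inner_join(imp3, imp6, by = "predictor")
  expect_gt(cor(merged$rank.x, merged$rank.y, method = "spearman"), 0.5)

  sweep <- mtry_sweep(cohort, mtry_values = c(2, 3), n_trees = 60,
                      n_repeats = 2, k_folds = 3, k_min = 3, n_boot = 200,
                      seed = 9)
  expect_named(sweep, c("mtry_2", "mtry_3"))
  for (run in sweep) {
    expect_s3_class(run$importance, "lpp_importance")
    expect_equal(nrow(run$importance), 32)
  }
})

test_that("averaging more forests stabilises the importance mean", {
  cohort <- signal_noise_cohort(n = 400, n_signal = 2, n_noise = 4,
                                seed = 8)
  mean_of <- function(n_repeats, seed) {
    imp <- average_importance(cohort, mtry = 2, n_trees = 50,
                              n_repeats = n_repeats, seed = seed)
    imp$mean_importance[imp$predictor == "Sig1"]
  }
  m5 <- vapply(1:10, function(s) mean_of(5, 100 + s), numeric(1))
  m25 <- vapply(1:10, function(s) mean_of(25, 200 + s), numeric(1))
  # SD of the repeat-mean should shrink roughly like 1/sqrt(n_repeats);
  # sqrt(25/5) ~ 2.2, allow a wide band around it
  ratio <- sd(m5) / sd(m25)
  expect_gt(ratio, 1.2)
})

test_that("importance ranks track the generating effect sizes
           directionally", {
  specs <- default_predictor_specs()
  cohort <- generate_cohort(specs, n = 1500, seed = 13)
  imp <- average_importance(cohort, mtry = 6, n_trees = 200, n_repeats = 2,
                            seed = 14)
  # expected discriminative strength grows with |beta| and with variance
  # p(1-p) of the predictor; ranks (1 = best) should correlate negatively
  strength <- abs(specs$beta) * specs$prevalence * (1 - specs$prevalence)
  merged <- dplyr::inner_join(imp, dplyr::select(specs, predictor = name),
                              by = "predictor")
  rho <- cor(strength[match(imp$predictor, specs$name)], imp$rank,
             method = "spearman")
  expect_lt(rho, 0)
})
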