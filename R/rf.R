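#' Averaged permutation variable importance over repeated forests
#'
#' Permutation importance from a single forest is noisy; stability is gained
#' by training `n_repeats` independent forests (distinct derived seeds) and
#' averaging each predictor's importance across them. Importance is the
#' unscaled out-of-bag permutation measure: the mean over trees of the drop
#' in out-of-bag accuracy when the predictor's values are permuted among
#' that tree's out-of-bag subjects (`randomForest::importance(type = 1,
#' scale = FALSE)`). The scaled variant (divided by its SD) is deliberately
#' not used, as it distorts comparisons between predictors.
#'
#' Reference settings for a definitive analysis are 25 repeats of 10,000
#' trees; the defaults here are scaled down for interactive use.
#'
#' @param data Cohort tibble (`subject_id` optional, 0/1 predictors,
#'   `outcome`).
#' @param mtry Candidate predictors per split.
#' @param n_trees Trees per forest.
#' @param n_repeats Number of independent forests averaged.
#' @param seed Integer seed; repeat `r` uses `derive_seed(seed, r)`.
#' @param outcome Outcome column name.
#' @return A tibble of class `lpp_importance`: `predictor`,
#'   `mean_importance`, `sd_importance`, `rank` (1 = highest mean; ties
#'   broken lexicographically by name).
#' @export
average_importance <- function(data, mtry = 6, n_trees = 500, n_repeats = 5,
                               seed = 1, outcome = "outcome") {
  assert_binary_dataset(data, outcome)
  preds <- predictor_columns(data, outcome)
  stopifnot(mtry >= 1, mtry <= length(preds))
  X <- as.matrix(data[preds])
  y <- factor(data[[outcome]], levels = c(0, 1))
  imp <- vapply(seq_len(n_repeats), function(r) {
    withr::with_seed(derive_seed(seed, r), {
      rf <- randomForest::randomForest(X, y, ntree = n_trees, mtry = mtry,
                                       importance = TRUE)
      randomForest::importance(rf, type = 1, scale = FALSE)[preds, 1]
    })
  }, numeric(length(preds)))
  imp <- matrix(imp, nrow = length(preds),
                dimnames = list(preds, NULL))
  out <- tibble::tibble(
    predictor = preds,
    mean_importance = rowMeans(imp),
    sd_importance = apply(imp, 1, sd)
  )
  out <- out[order(-out$mean_importance, out$predictor), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("lpp_importance", class(out))
  out
}

#' Drop predictors with non-positive averaged importance
#'
#' After importance averaging, predictors whose mean permutation importance
#' is negative carry no usable signal and are removed before the sequential
#' selection stage. Exactly-zero importance is treated as non-positive and
#' removed too.
#'
#' @param importance An `lpp_importance` table.
#' @return Character vector of retained predictor names in rank order
#'   (best first); a warning is raised if nothing survives.
#' @export
filter_negative <- function(importance) {
  keep <- importance$predictor[importance$mean_importance > 0]
  if (length(keep) == 0L) {
    warning("no predictor has positive mean importance; nothing selectable")
  }
  keep
}

# train one forest on the given predictors and score new data (class-1 vote
# fraction); mtry is capped at the number of predictors
.train_score_rf <- function(train, test, predictors, mtry, n_trees, seed,
                            outcome = "outcome") {
  Xtr <- as.matrix(train[predictors])
  ytr <- factor(train[[outcome]], levels = c(0, 1))
  Xte <- as.matrix(test[predictors])
  withr::with_seed(seed, {
    rf <- randomForest::randomForest(
      Xtr, ytr, ntree = n_trees, mtry = min(mtry, length(predictors))
    )
    unname(predict(rf, Xte, type = "prob")[, "1"])
  })
}

#' Out-of-fold random-forest predictions
#'
#' Stratified K-fold cross-validation: each subject is scored (class-1 vote
#' fraction) by the forest trained without its fold. The fold assignment is
#' returned so that nested models can reuse it — a paired DeLong comparison
#' is only valid when every model scores the same subjects under the same
#' folds.
#'
#' @inheritParams average_importance
#' @param predictors Predictor names to use (`NULL` = all).
#' @param k_folds Number of folds (default 10).
#' @param folds Optional precomputed fold assignment (from [make_folds()]);
#'   when supplied, `seed` only drives forest training.
#' @return A tibble of class `lpp_cv_predictions`: `row_id`, `fold`,
#'   `score`, `label`; the assignment is in `attr(, "folds")`.
#' @export
cv_forest_predictions <- function(data, predictors = NULL, mtry = 6,
                                  n_trees = 500, k_folds = 10, seed = 1,
                                  folds = NULL, outcome = "outcome") {
  assert_binary_dataset(data, outcome)
  predictors <- predictors %||% predictor_columns(data, outcome)
  stopifnot(all(predictors %in% names(data)), k_folds >= 2)
  y <- data[[outcome]]
  folds <- folds %||% make_folds(y, k_folds, derive_seed(seed, 0L))
  scores <- numeric(nrow(data))
  for (f in sort(unique(folds))) {
    test_idx <- folds == f
    scores[test_idx] <- .train_score_rf(
      data[!test_idx, , drop = FALSE], data[test_idx, , drop = FALSE],
      predictors, mtry, n_trees, derive_seed(seed, f), outcome
    )
  }
  out <- tibble::tibble(
    row_id = seq_len(nrow(data)),
    fold = folds,
    score = scores,
    label = y
  )
  attr(out, "folds") <- folds
  class(out) <- c("lpp_cv_predictions", class(out))
  out
}

#' Sequential ranked-predictor selection with a parsimonious-model rule
#'
#' Builds nested forests on the top `k` ranked predictors for
#' `k = k_min, ..., length(ranked)`, scoring each by pooled out-of-fold AUC
#' with a stratified-bootstrap CI, and compares each against the full
#' reference model (ALL candidate predictors in `data`, not just the
#' positive-importance ones) with DeLong's paired test on the shared folds.
#' The selected model is the smallest `k` whose AUC does not differ
#' significantly from the full model's (`p >= alpha`); when no `k`
#' qualifies, `chosen_k` is `NA` — every sub-model is significantly worse
#' than the full model.
#'
#' @inheritParams cv_forest_predictions
#' @param ranked Predictor names in importance-rank order (typically
#'   [filter_negative()] output).
#' @param alpha Significance level of the parsimonious-model rule.
#' @param k_min Smallest sub-model size considered (default 3).
#' @param n_boot Bootstrap replicates for each CI.
#' @return An object of class `lpp_rf_selection`: list with `nested`
#'   (tibble: `k`, `auc`, `ci_low`, `ci_high`, `delong_p`), `chosen_k`,
#'   `retained`, `ranked`, `full_auc` (one-row tibble), `mtry`, `folds`.
#' @export
sequential_selection <- function(data, ranked, mtry = 6, n_trees = 500,
                                 k_folds = 10, alpha = 0.05, k_min = 3,
                                 n_boot = 500, seed = 1,
                                 outcome = "outcome") {
  assert_binary_dataset(data, outcome)
  stopifnot(length(ranked) >= 1, k_min >= 1)
  all_preds <- predictor_columns(data, outcome)
  folds <- make_folds(data[[outcome]], k_folds, derive_seed(seed, 0L))
  full_cv <- cv_forest_predictions(data, all_preds, mtry, n_trees, k_folds,
                                   derive_seed(seed, 1L), folds, outcome)
  full_auc <- stratified_bootstrap_ci(full_cv, n_boot = n_boot,
                                      seed = derive_seed(seed, 2L))
  ks <- seq(min(k_min, length(ranked)), length(ranked))
  nested <- purrr::map_dfr(ks, function(k) {
    # a sub-model on the complete candidate set IS the full model: reuse its
    # scores so the DeLong self-comparison is exact (z = 0, p = 1)
    cv_k <- if (setequal(ranked[seq_len(k)], all_preds)) {
      full_cv
    } else {
      cv_forest_predictions(data, ranked[seq_len(k)], mtry, n_trees,
                            k_folds, derive_seed(seed, 10L + k),
                            folds, outcome)
    }
    est <- stratified_bootstrap_ci(cv_k, n_boot = n_boot,
                                   seed = derive_seed(seed, 1000L + k))
    cmp <- .delong_test(cv_k$score, full_cv$score, cv_k$label)
    tibble::tibble(k = k, auc = est$auc, ci_low = est$ci_low,
                   ci_high = est$ci_high, delong_p = cmp$p_value)
  })
  qualifying <- nested$k[nested$delong_p >= alpha]
  chosen_k <- if (length(qualifying)) min(qualifying) else NA_integer_
  structure(
    list(
      nested = nested,
      chosen_k = chosen_k,
      retained = if (is.na(chosen_k)) character(0)
                 else ranked[seq_len(chosen_k)],
      ranked = ranked,
      full_auc = full_auc,
      mtry = mtry,
      alpha = alpha,
      folds = folds
    ),
    class = "lpp_rf_selection"
  )
}

#' Run the full forest selection procedure over several mtry values
#'
#' For each `mtry`: averaged importance over repeated forests, removal of
#' non-positive-importance predictors, then sequential nested-model
#' selection against the all-predictor reference. Each `mtry` uses an
#' independent derived seed.
#'
#' @inheritParams sequential_selection
#' @param mtry_values Integer vector; the canonical sweep is `c(3, 6, 16)`
#'   (small, `sqrt(p)` default, large).
#' @param n_repeats Forests averaged per importance table.
#' @return An object of class `lpp_mtry_sweep`: named list (one element per
#'   mtry) of lists with `importance` and `selection`.
#' @export
mtry_sweep <- function(data, mtry_values = c(3, 6, 16), n_trees = 500,
                       n_repeats = 5, k_folds = 10, alpha = 0.05, k_min = 3,
                       n_boot = 500, seed = 1, outcome = "outcome") {
  runs <- purrr::map(seq_along(mtry_values), function(i) {
    m <- mtry_values[i]
    imp <- average_importance(data, mtry = m, n_trees = n_trees,
                              n_repeats = n_repeats,
                              seed = derive_seed(seed, 100L + i),
                              outcome = outcome)
    ranked <- filter_negative(imp)
    sel <- if (length(ranked)) {
      sequential_selection(data, ranked, mtry = m, n_trees = n_trees,
                           k_folds = k_folds, alpha = alpha, k_min = k_min,
                           n_boot = n_boot, seed = derive_seed(seed, 200L + i),
                           outcome = outcome)
    } else {
      NULL
    }
    list(importance = imp, selection = sel)
  })
  names(runs) <- paste0("mtry_", mtry_values)
  structure(runs, mtry_values = mtry_values, class = "lpp_mtry_sweep")
}

#' @export
print.lpp_rf_selection <- function(x, ...) {
  cat("Random-forest sequential selection (mtry =", x$mtry, ")\n")
  cat("  candidates ranked (positive importance):", length(x$ranked), "\n")
  cat("  full-model AUC:", sprintf("%.3f (%.3f, %.3f)", x$full_auc$auc,
                                   x$full_auc$ci_low, x$full_auc$ci_high),
      "\n")
  if (is.na(x$chosen_k)) {
    cat("  no sub-model matches the full model at alpha =", x$alpha, "\n")
  } else {
    row <- x$nested[x$nested$k == x$chosen_k, ]
    cat("  parsimonious model: k =", x$chosen_k,
        sprintf("AUC %.3f (%.3f, %.3f), DeLong p = %.3f", row$auc,
                row$ci_low, row$ci_high, row$delong_p), "\n")
  }
  invisible(x)
}
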