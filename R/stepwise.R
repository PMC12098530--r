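# Fast AIC of a logistic fit on a fixed design matrix (intercept included).
# Used by the greedy stepwise loop, where thousands of candidate fits are
# evaluated; glm.fit avoids formula overhead. Returns +Inf if the fit errors.
.logit_aic <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                             family = binomial())),
    error = function(e) NULL
  )
  if (is.null(fit)) return(Inf)
  fit$aic
}

#' Fit a logistic regression on a fixed predictor set
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' binary outcome on the named predictors. Constant predictor columns are
#' dropped with a warning and recorded. Separation — rare predictors that
#' perfectly split the outcome drive coefficients to infinity — is flagged
#' when any |coefficient| exceeds 15 on the log-odds scale or the fit does
#' not converge; flagged fits are reported as-is (no penalised fallback),
#' with their Wald intervals marked unreliable.
#'
#' @param data Cohort tibble with 0/1 predictors and an `outcome` column.
#' @param predictors Predictor names (`NULL` = all).
#' @param outcome Outcome column name.
#' @param separation_bound Log-odds magnitude beyond which a coefficient is
#'   taken as evidence of separation.
#' @return An object of class `lpp_logit`: list with `fit` (the `glm`),
#'   `predictors`, `dropped`, `coefficients`, `std_errors`, `intercept`,
#'   `log_likelihood`, `aic`, `converged`, `separation_flag`, `n`.
#' @export
fit_logistic <- function(data, predictors = NULL, outcome = "outcome",
                         separation_bound = 15) {
  assert_binary_dataset(data, outcome)
  predictors <- predictors %||% predictor_columns(data, outcome)
  stopifnot(all(predictors %in% names(data)))
  if (nrow(data) <= length(predictors) + 1) {
    stop("need n > number of predictors + 1")
  }
  constant <- predictors[vapply(predictors,
                                function(p) length(unique(data[[p]])) < 2L,
                                logical(1))]
  if (length(constant)) {
    warning("dropping constant predictor(s): ",
            paste(constant, collapse = ", "))
    predictors <- setdiff(predictors, constant)
  }
  df <- data.frame(data[c(predictors, outcome)], check.names = FALSE)
  fml <- stats::reformulate(
    if (length(predictors)) sprintf("`%s`", predictors) else "1",
    response = sprintf("`%s`", outcome)
  )
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  alias <- is.na(coef(fit))
  if (any(alias)) {
    stop("singular design; collinear term(s): ",
         paste(names(coef(fit))[alias], collapse = ", "))
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  betas <- cf[setdiff(names(cf), "(Intercept)")]
  names(betas) <- predictors
  structure(
    list(
      fit = fit,
      predictors = predictors,
      dropped = constant,
      coefficients = betas,
      std_errors = setNames(se[setdiff(names(cf), "(Intercept)")],
                            predictors),
      intercept = unname(cf["(Intercept)"]),
      log_likelihood = as.numeric(logLik(fit)),
      aic = fit$aic,
      converged = fit$converged,
      separation_flag = !fit$converged || any(abs(cf) > separation_bound),
      n = nrow(data)
    ),
    class = "lpp_logit"
  )
}

#' Wald odds ratios with confidence intervals
#'
#' `OR = exp(coef)` with `exp(coef +/- z * SE)` intervals. When the fit is
#' separation-flagged the intervals are still emitted but marked unreliable
#' (`reliable = FALSE`) — rare predictors with huge unstable estimates are a
#' reported finding, not an error.
#'
#' @param fit An `lpp_logit` object.
#' @param alpha Two-sided miscoverage (0.05 gives 95% CIs).
#' @return A tibble: `term`, `odds_ratio`, `ci_low`, `ci_high`, `estimate`
#'   (log-odds), `std_error`, `reliable`.
#' @export
wald_odds_ratios <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lpp_logit"))
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(
    term = fit$predictors,
    odds_ratio = exp(unname(fit$coefficients)),
    ci_low = exp(unname(fit$coefficients) - z * unname(fit$std_errors)),
    ci_high = exp(unname(fit$coefficients) + z * unname(fit$std_errors)),
    estimate = unname(fit$coefficients),
    std_error = unname(fit$std_errors),
    reliable = !fit$separation_flag
  )
}

# One greedy AIC pass. direction "backward" starts from `candidates` and
# removes; "forward" starts empty and adds. AIC ties within `tol` prefer the
# smaller model (remove on tie, refuse to add on tie); equal-AIC candidate
# moves break lexicographically by name.
.stepwise <- function(data, candidates, outcome, direction, tol = 1e-8) {
  X_all <- as.matrix(data[candidates])
  y <- data[[outcome]]
  current <- if (direction == "backward") candidates else character(0)
  aic_of <- function(set) {
    .logit_aic(X_all[, set, drop = FALSE], y)
  }
  current_aic <- aic_of(current)
  trajectory <- tibble::tibble(
    step = 0L, action = "start", predictor = NA_character_,
    aic = current_aic
  )
  step <- 0L
  repeat {
    pool <- if (direction == "backward") current
            else setdiff(candidates, current)
    if (length(pool) == 0L) break
    pool <- sort(pool)
    cand_aic <- vapply(pool, function(p) {
      set <- if (direction == "backward") setdiff(current, p)
             else c(current, p)
      aic_of(set)
    }, numeric(1))
    best <- which.min(cand_aic) # first minimum = lexicographic tie-break
    improve <- if (direction == "backward") {
      cand_aic[best] <= current_aic + tol # tie -> prefer smaller model
    } else {
      cand_aic[best] < current_aic - tol
    }
    if (!improve) break
    step <- step + 1L
    if (direction == "backward") {
      current <- setdiff(current, pool[best])
      action <- "remove"
    } else {
      current <- c(current, pool[best])
      action <- "add"
    }
    current_aic <- cand_aic[[best]]
    trajectory <- dplyr::bind_rows(
      trajectory,
      tibble::tibble(step = step, action = action, predictor = pool[best],
                     aic = current_aic)
    )
  }
  list(retained = current, trajectory = trajectory)
}

#' Backward stepwise logistic regression under AIC
#'
#' Starts from the model with every candidate predictor and greedily removes
#' the single predictor whose removal lowers AIC most, stopping when no
#' removal lowers AIC. AIC ties (within `1e-8`) are resolved in favour of
#' the smaller model; tied candidate removals break lexicographically, so
#' reruns are deterministic. No p-value stopping rule is used anywhere.
#'
#' Selection runs once on the full data; the retained set is then assessed
#' by 10-fold cross-validation as a *fixed* set (selection is not re-run per
#' fold), which mirrors common practice but carries a known optimism that
#' the methods vignette discusses.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param k_folds,seed,n_boot Cross-validation and bootstrap settings for
#'   the AUC of the retained model; set `cv = FALSE` to skip.
#' @param cv Compute the cross-validated AUC of the retained model?
#' @return An object of class `lpp_stepwise`: list with `direction`,
#'   `retained` (ordered), `trajectory` (tibble: `step`, `action`,
#'   `predictor`, `aic`), `final_fit` (`lpp_logit`), `cv_auc` (one-row
#'   tibble or `NULL`).
#' @export
backward_stepwise <- function(data, outcome = "outcome", cv = TRUE,
                              k_folds = 10, seed = 1, n_boot = 2000) {
  .run_stepwise(data, outcome, "backward", cv, k_folds, seed, n_boot)
}

#' Forward stepwise logistic regression under AIC
#'
#' Starts from the intercept-only model and greedily adds the single
#' predictor lowering AIC most, stopping when no addition lowers AIC.
#' Tie handling and cross-validation as in [backward_stepwise()].
#'
#' @inheritParams backward_stepwise
#' @return An `lpp_stepwise` object; `retained` is in order of entry.
#' @export
forward_stepwise <- function(data, outcome = "outcome", cv = TRUE,
                             k_folds = 10, seed = 1, n_boot = 2000) {
  .run_stepwise(data, outcome, "forward", cv, k_folds, seed, n_boot)
}

.run_stepwise <- function(data, outcome, direction, cv, k_folds, seed,
                          n_boot) {
  assert_binary_dataset(data, outcome)
  candidates <- predictor_columns(data, outcome)
  res <- .stepwise(data, candidates, outcome, direction)
  final_fit <- if (length(res$retained)) {
    fit_logistic(data, res$retained, outcome)
  } else {
    NULL
  }
  cv_auc <- if (cv && length(res$retained)) {
    cv_logistic_auc(data, res$retained, k_folds = k_folds, seed = seed,
                    n_boot = n_boot, outcome = outcome)
  } else {
    NULL
  }
  structure(
    list(direction = direction, retained = res$retained,
         trajectory = res$trajectory, final_fit = final_fit,
         cv_auc = cv_auc),
    class = "lpp_stepwise"
  )
}

#' Cross-validated AUC of a fixed logistic model
#'
#' Refits the given (fixed) predictor set within each training fold and
#' pools the held-out predicted probabilities; the pooled scores are
#' summarised by Mann-Whitney AUC with a stratified-bootstrap CI. Fold-level
#' separation does not abort: the fold's predictions are still produced and
#' the fold is counted in `attr(, "flagged_folds")`.
#'
#' @param data Cohort tibble.
#' @param predictors Fixed predictor set to refit per fold.
#' @param k_folds Number of folds.
#' @param seed Integer seed (folds, forest-free here, and bootstrap).
#' @param n_boot Bootstrap replicates for the CI; `0` skips the bootstrap
#'   and returns only the point AUC (fast path for simulations).
#' @param alpha CI miscoverage.
#' @param outcome Outcome column name.
#' @param folds Optional precomputed fold assignment.
#' @return A one-row tibble (`auc`, `ci_low`, `ci_high`, `method`,
#'   `n_boot`, `alpha`), with the pooled predictions in
#'   `attr(, "predictions")`.
#' @export
cv_logistic_auc <- function(data, predictors, k_folds = 10, seed = 1,
                            n_boot = 2000, alpha = 0.05,
                            outcome = "outcome", folds = NULL) {
  assert_binary_dataset(data, outcome)
  stopifnot(all(predictors %in% names(data)), k_folds >= 2)
  y <- data[[outcome]]
  folds <- folds %||% make_folds(y, k_folds, derive_seed(seed, 0L))
  X <- as.matrix(data[predictors])
  scores <- numeric(nrow(data))
  flagged <- integer(0)
  for (f in sort(unique(folds))) {
    test_idx <- folds == f
    Xtr <- cbind(1, X[!test_idx, , drop = FALSE])
    fit <- suppressWarnings(glm.fit(Xtr, y[!test_idx], family = binomial()))
    cf <- fit$coefficients
    if (!fit$converged || any(abs(cf) > 15, na.rm = TRUE)) {
      flagged <- c(flagged, f)
    }
    cf[is.na(cf)] <- 0 # rank-deficient fold fits: aliased terms contribute 0
    scores[test_idx] <- plogis(drop(cbind(1, X[test_idx, , drop = FALSE])
                                    %*% cf))
  }
  preds <- tibble::tibble(row_id = seq_len(nrow(data)), fold = folds,
                          score = scores, label = y)
  out <- if (n_boot > 0) {
    stratified_bootstrap_ci(preds, n_boot = n_boot, alpha = alpha,
                            seed = derive_seed(seed, 99L))
  } else {
    tibble::tibble(auc = .auc_mw(scores, y), ci_low = NA_real_,
                   ci_high = NA_real_, method = "none",
                   n_boot = 0L, alpha = alpha)
  }
  attr(out, "predictions") <- preds
  attr(out, "flagged_folds") <- flagged
  out
}

#' @export
print.lpp_stepwise <- function(x, ...) {
  cat(x$direction, "stepwise logistic regression (AIC)\n")
  cat("  retained:", length(x$retained), "predictor(s)\n")
  if (!is.null(x$final_fit)) {
    cat("  final AIC:", sprintf("%.2f", x$final_fit$aic), "\n")
  }
  if (!is.null(x$cv_auc)) {
    cat("  cross-validated AUC:",
        sprintf("%.3f (%.3f, %.3f)", x$cv_auc$auc, x$cv_auc$ci_low,
                x$cv_auc$ci_high), "\n")
  }
  invisible(x)
}

#' @export
print.lpp_logit <- function(x, ...) {
  cat("logistic fit:", length(x$predictors), "predictor(s), n =", x$n, "\n")
  cat("  AIC:", sprintf("%.2f", x$aic),
      " logLik:", sprintf("%.2f", x$log_likelihood), "\n")
  if (x$separation_flag) cat("  WARNING: separation suspected\n")
  invisible(x)
}
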