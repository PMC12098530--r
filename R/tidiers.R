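#' Tidy a logistic fit
#'
#' One row per predictor with log-odds estimate, Wald statistics and odds
#' ratio with confidence interval.
#'
#' @param x An `lpp_logit` object.
#' @param conf_level Confidence level for the OR interval.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `odds_ratio`, `conf_low`, `conf_high`.
#' @export
tidy.lpp_logit <- function(x, conf_level = 0.95, ...) {
  or <- wald_odds_ratios(x, alpha = 1 - conf_level)
  z <- or$estimate / or$std_error
  tibble::tibble(
    term = or$term,
    estimate = or$estimate,
    std_error = or$std_error,
    statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    odds_ratio = or$odds_ratio,
    conf_low = or$ci_low,
    conf_high = or$ci_high
  )
}

#' Glance at a logistic fit
#' @param x An `lpp_logit` object.
#' @param ... Unused.
#' @return A one-row tibble: `nobs`, `n_predictors`, `log_likelihood`,
#'   `aic`, `converged`, `separation_flag`.
#' @export
glance.lpp_logit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    n_predictors = length(x$predictors),
    log_likelihood = x$log_likelihood,
    aic = x$aic,
    converged = x$converged,
    separation_flag = x$separation_flag
  )
}

#' Tidy a stepwise result
#'
#' Returns the per-predictor odds-ratio table of the final retained model.
#'
#' @param x An `lpp_stepwise` object.
#' @param ... Passed to [tidy.lpp_logit()].
#' @return A tibble as in [tidy.lpp_logit()]; zero rows if nothing was
#'   retained.
#' @export
tidy.lpp_stepwise <- function(x, ...) {
  if (is.null(x$final_fit)) {
    return(tidy.lpp_logit(structure(list(predictors = character(0)),
                                    class = "lpp_logit"))[0, ])
  }
  tidy.lpp_logit(x$final_fit, ...)
}

#' Glance at a stepwise result
#' @param x An `lpp_stepwise` object.
#' @param ... Unused.
#' @return A one-row tibble: `direction`, `n_retained`, `n_steps`, `aic`,
#'   `cv_auc`, `cv_ci_low`, `cv_ci_high`.
#' @export
glance.lpp_stepwise <- function(x, ...) {
  tibble::tibble(
    direction = x$direction,
    n_retained = length(x$retained),
    n_steps = max(x$trajectory$step),
    aic = if (is.null(x$final_fit)) NA_real_ else x$final_fit$aic,
    cv_auc = if (is.null(x$cv_auc)) NA_real_ else x$cv_auc$auc,
    cv_ci_low = if (is.null(x$cv_auc)) NA_real_ else x$cv_auc$ci_low,
    cv_ci_high = if (is.null(x$cv_auc)) NA_real_ else x$cv_auc$ci_high
  )
}

#' Tidy a forest selection result
#'
#' Returns the nested-model table: one row per sub-model size `k` with its
#' pooled out-of-fold AUC, bootstrap CI and DeLong p against the full model.
#'
#' @param x An `lpp_rf_selection` object.
#' @param ... Unused.
#' @return A tibble: `k`, `auc`, `ci_low`, `ci_high`, `delong_p`, `chosen`.
#' @export
tidy.lpp_rf_selection <- function(x, ...) {
  out <- x$nested
  out$chosen <- !is.na(x$chosen_k) & out$k == x$chosen_k
  out
}

#' Glance at a forest selection result
#' @param x An `lpp_rf_selection` object.
#' @param ... Unused.
#' @return A one-row tibble: `mtry`, `n_candidates`, `chosen_k`,
#'   `full_auc`, `full_ci_low`, `full_ci_high`.
#' @export
glance.lpp_rf_selection <- function(x, ...) {
  tibble::tibble(
    mtry = x$mtry,
    n_candidates = length(x$ranked),
    chosen_k = x$chosen_k,
    full_auc = x$full_auc$auc,
    full_ci_low = x$full_auc$ci_low,
    full_ci_high = x$full_auc$ci_high
  )
}
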