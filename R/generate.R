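#' Calibrate the outcome-model intercept to a target prevalence
#'
#' The cohort generator draws the outcome from a logistic model
#' `P(y = 1 | x) = plogis(b0 + sum(beta_j * x_j))`. Because the betas are
#' fixed (they are the quantity under study), the marginal outcome prevalence
#' is controlled through the intercept `b0`. This function finds, by
#' root-search over a Monte-Carlo sample of predictor draws, the intercept at
#' which the expected outcome prevalence equals `target_prevalence`.
#'
#' With all betas zero the result is the closed form
#' `qlogis(target_prevalence)`.
#'
#' @param specs Predictor specification tibble.
#' @param target_prevalence Desired marginal outcome prevalence in (0, 1);
#'   the default matches a 15.1% sepsis rate.
#' @param n_mc Monte-Carlo sample size for the predictor draws (>= 10^4).
#' @param seed Integer seed; the result is deterministic given it.
#' @return The calibrated intercept (log-odds scale).
#' @examples
#' calibrate_intercept(default_predictor_specs(), 0.151, n_mc = 1e4, seed = 1)
#' @export
calibrate_intercept <- function(specs, target_prevalence = 0.151,
                                n_mc = 2e5, seed = 1) {
  specs <- validate_predictor_specs(specs)
  stopifnot(target_prevalence > 0, target_prevalence < 1, n_mc >= 1e4)
  eta <- withr::with_seed(seed, {
    X <- vapply(specs$prevalence, function(p) rbinom(n_mc, 1L, p),
                integer(n_mc))
    drop(X %*% specs$beta)
  })
  f <- function(b0) mean(plogis(b0 + eta)) - target_prevalence
  # mean(plogis(b0 + eta)) is strictly increasing in b0 with limits 0 and 1,
  # so a root always exists; widen the bracket geometrically if needed
  lo <- -40; hi <- 40
  for (i in 1:10) {
    if (f(lo) < 0 && f(hi) > 0) break
    lo <- lo * 2; hi <- hi * 2
    if (i == 10) stop("intercept bracketing failed to converge")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic binary-predictor cohort
#'
#' Draws `n` subjects with independent Bernoulli predictor columns at the
#' spec prevalences and a Bernoulli outcome from the logistic model
#' `plogis(intercept + X %*% beta)`. Output is bitwise-reproducible for a
#' given seed. If the realised outcome is single-class the cohort is flagged
#' degenerate (see [is_degenerate_cohort()]); callers that need a usable
#' cohort should regenerate with the next derived seed.
#'
#' @param specs Predictor specification tibble.
#' @param n Number of subjects (default 3473).
#' @param intercept Outcome-model intercept on the log-odds scale; if `NULL`
#'   it is calibrated to `target_prevalence` via [calibrate_intercept()].
#' @param target_prevalence Target marginal outcome prevalence used when
#'   `intercept` is `NULL`.
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, one 0/1 column per predictor
#'   (in spec order), and `outcome`; the intercept used is stored in
#'   `attr(, "intercept")`.
#' @examples
#' cohort <- generate_cohort(default_predictor_specs(), n = 500, seed = 1)
#' mean(cohort$outcome)
#' @export
generate_cohort <- function(specs, n = 3473, intercept = NULL,
                            target_prevalence = 0.151, seed = 1) {
  specs <- validate_predictor_specs(specs)
  stopifnot(n >= 2)
  if (is.null(intercept)) {
    intercept <- calibrate_intercept(specs, target_prevalence,
                                     seed = derive_seed(seed, 0L))
  }
  cohort <- withr::with_seed(seed, {
    X <- vapply(specs$prevalence, function(p) rbinom(n, 1L, p), integer(n))
    colnames(X) <- specs$name
    y <- rbinom(n, 1L, plogis(intercept + drop(X %*% specs$beta)))
    dplyr::bind_cols(
      tibble::tibble(subject_id = seq_len(n)),
      tibble::as_tibble(X),
      tibble::tibble(outcome = y)
    )
  })
  attr(cohort, "intercept") <- intercept
  cohort
}

#' Is a cohort degenerate?
#'
#' A cohort is degenerate when the outcome column has a single class; no
#' classifier or ROC statistic is defined on it.
#'
#' @param cohort A cohort tibble with an `outcome` column.
#' @return `TRUE`/`FALSE`.
#' @export
is_degenerate_cohort <- function(cohort) {
  length(unique(cohort$outcome)) < 2L
}

# generate, regenerating on the (very rare) degenerate outcome; returns the
# cohort plus the number of regenerations
generate_cohort_safe <- function(specs, n, intercept, seed, max_tries = 20L) {
  for (attempt in seq_len(max_tries)) {
    s <- if (attempt == 1L) seed else derive_seed(seed, 1000L + attempt)
    cohort <- generate_cohort(specs, n = n, intercept = intercept, seed = s)
    if (!is_degenerate_cohort(cohort)) {
      return(list(cohort = cohort, regenerated = attempt - 1L))
    }
  }
  stop("could not generate a non-degenerate cohort in ", max_tries, " tries")
}

#' Read / write cohorts as CSV
#'
#' Cohorts are exchanged as CSV with a `subject_id,<predictors...>,outcome`
#' header and strictly 0/1 values; [read_cohort()] validates that contract.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  if (names(cohort)[1] != "subject_id" ||
      names(cohort)[ncol(cohort)] != "outcome") {
    stop("cohort CSV must have `subject_id` first and `outcome` last")
  }
  assert_binary_dataset(cohort)
  cohort
}
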