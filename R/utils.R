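#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from one master seed; child seeds for
#' repeats, folds, datasets and bootstrap draws are derived with a
#' counter-based linear-congruential scheme so that any single unit of work
#' is reproducible in isolation. Scheme id: `"lcg-48271-v1"`.
#'
#' @param master Integer master seed.
#' @param ... Integer counters identifying the unit of work (e.g. threshold
#'   index, dataset index, attempt number).
#' @return A single integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- abs(as.double(master)) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + (abs(as.double(k)) + 1) * 8191 + 1) %% 2147483647
  }
  as.integer(x) + 1L
}

seed_scheme_id <- function() "lcg-48271-v1"

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k_folds` folds, stratified by class so
#' fold-level class proportions track the overall prevalence. If any fold
#' ends up with a single outcome class the assignment is regenerated with the
#' next derived seed (rare under stratification; only possible when a class
#' has fewer members than folds).
#'
#' @param labels Vector of 0/1 outcome labels.
#' @param k_folds Number of folds (at least 2).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @param max_tries Regeneration budget before erroring.
#' @return Integer vector of fold indices in `1..k_folds`.
#' @export
make_folds <- function(labels, k_folds, seed, max_tries = 100L) {
  stopifnot(k_folds >= 2, length(labels) >= k_folds)
  for (try in seq_len(max_tries)) {
    fold <- withr::with_seed(derive_seed(seed, try), {
      f <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        f[idx] <- sample(rep_len(sample.int(k_folds), length(idx)))
      }
      f
    })
    ok <- all(tabulate(fold, k_folds) > 0) &&
      all(vapply(split(labels, fold), function(y) length(unique(y)) == 2L,
                 logical(1)))
    if (ok) return(fold)
  }
  stop("could not build stratified folds with both classes in every fold; ",
       "reduce `k_folds` or check the outcome distribution")
}

# quantile of an integer-valued empirical distribution given as counts
counts_quantile <- function(values, counts, probs) {
  o <- order(values)
  values <- values[o]
  counts <- counts[o]
  n <- sum(counts)
  cum <- cumsum(counts)
  vapply(probs, function(p) {
    # type-1 (inverse ECDF) quantile: smallest value with F(x) >= p
    values[which(cum >= p * n)[1]]
  }, numeric(1))
}

predictor_columns <- function(data, outcome = "outcome") {
  setdiff(names(data), c("subject_id", outcome))
}

assert_binary_dataset <- function(data, outcome = "outcome") {
  if (!outcome %in% names(data)) {
    stop("no `", outcome, "` column in the dataset")
  }
  cols <- c(predictor_columns(data, outcome), outcome)
  bad <- cols[!vapply(cols, function(cl) {
    v <- data[[cl]]
    is.numeric(v) && !anyNA(v) && all(v %in% c(0, 1))
  }, logical(1))]
  if (length(bad)) {
    stop("non-binary or missing values in column(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(unique(data[[outcome]])) < 2) {
    stop("degenerate dataset: outcome has a single class")
  }
  invisible(data)
}
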