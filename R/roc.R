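#' ROC statistics on paired hold-out predictions
#'
#' These functions operate on "scored outcome" data: one row per subject
#' with a continuous score (typically a pooled out-of-fold predicted
#' probability) and the true 0/1 label. The AUC is the Mann-Whitney
#' estimator — the probability that a random positive outscores a random
#' negative, ties half-credited — which equals the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param data A data frame with one row per subject.
#' @param score,label Column names (strings) holding the score and the 0/1
#'   label.
#' @return `auc_mann_whitney()` returns a single number in `[0, 1]`.
#' @examples
#' d <- tibble::tibble(score = c(0.9, 0.8, 0.7, 0.85), label = c(1, 1, 0, 0))
#' auc_mann_whitney(d) # 0.75
#' @export
auc_mann_whitney <- function(data, score = "score", label = "label") {
  .auc_mw(data[[score]], data[[label]])
}

.check_scored <- function(scores, labels) {
  if (anyNA(scores) || !all(is.finite(scores))) stop("scores must be finite")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0L || n == 0L) {
    stop("AUC undefined: need at least one positive and one negative label")
  }
  c(pos = m, neg = n)
}

.auc_mw <- function(scores, labels) {
  cnt <- .check_scored(scores, labels)
  m <- cnt[["pos"]]
  n <- cnt[["neg"]]
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (as.double(m) * n)
}

#' Placement values for DeLong's method
#'
#' For each positive subject the placement value is the fraction of
#' negatives it outscores (ties half-credited); symmetrically for negatives.
#' The mean of either vector equals the Mann-Whitney AUC. These are the
#' per-subject components whose sample (co)variances drive DeLong's test.
#'
#' @inheritParams auc_mann_whitney
#' @return A list with numeric vectors `v_pos` (one per positive, in row
#'   order) and `v_neg` (one per negative).
#' @export
delong_components <- function(data, score = "score", label = "label") {
  .placements(data[[score]], data[[label]])
}

.placements <- function(scores, labels) {
  .check_scored(scores, labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  list(
    v_pos = (r_all[seq_len(m)] - r_pos) / n,
    v_neg = 1 - (r_all[m + seq_len(n)] - r_neg) / m
  )
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two scores computed on the same subjects (a paired
#' design: identical labels, identical subject order), using the asymptotic
#' normal theory of placement-value (co)variances. The test is two-sided.
#' When the variance of the AUC difference is numerically zero (e.g. the two
#' scores are identical) the statistic is defined as `z = 0`, `p = 1`.
#'
#' @param data A data frame with one row per subject.
#' @param score1,score2 Column names of the two scores to compare.
#' @param label Column name of the shared 0/1 label.
#' @return A one-row tibble: `auc1`, `auc2`, `var1`, `var2`, `cov12`
#'   (variances/covariance of the AUC estimators), `z`, `p_value`.
#' @examples
#' d <- tibble::tibble(a = c(0.9, 0.8, 0.7, 0.85),
#'                     b = c(0.9, 0.8, 0.7, 0.85),
#'                     label = c(1, 1, 0, 0))
#' delong_paired_test(d, "a", "b") # z = 0, p = 1
#' @export
delong_paired_test <- function(data, score1 = "score1", score2 = "score2",
                               label = "label") {
  s1 <- data[[score1]]
  s2 <- data[[score2]]
  y <- data[[label]]
  p1 <- .placements(s1, y)
  p2 <- .placements(s2, y)
  m <- length(p1$v_pos)
  n <- length(p1$v_neg)
  auc1 <- mean(p1$v_pos)
  auc2 <- mean(p2$v_pos)
  var1 <- var(p1$v_pos) / m + var(p1$v_neg) / n
  var2 <- var(p2$v_pos) / m + var(p2$v_neg) / n
  cov12 <- cov(p1$v_pos, p2$v_pos) / m + cov(p1$v_neg, p2$v_neg) / n
  v_diff <- var1 + var2 - 2 * cov12
  if (v_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- (auc1 - auc2) / sqrt(v_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc1 = auc1, auc2 = auc2, var1 = var1, var2 = var2,
                 cov12 = cov12, z = z, p_value = p)
}

# paired test on two score vectors sharing one label vector (internal)
.delong_test <- function(s1, s2, labels) {
  delong_paired_test(
    tibble::tibble(score1 = s1, score2 = s2, label = labels)
  )
}

#' Stratified-bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives separately with replacement (class
#' counts preserved, so no replicate can lose a class) and returns the
#' percentile interval of the replicate AUCs. Endpoints are clamped to
#' bracket the point estimate so the interval always contains the reported
#' AUC.
#'
#' @inheritParams auc_mann_whitney
#' @param n_boot Number of bootstrap replicates (>= 200; default 2000).
#' @param alpha Two-sided miscoverage; 0.05 gives a 95% interval.
#' @param seed Integer seed; deterministic given it.
#' @return A one-row tibble: `auc`, `ci_low`, `ci_high`, `method`
#'   (`"stratified_bootstrap"`), `n_boot`, `alpha`.
#' @export
stratified_bootstrap_ci <- function(data, score = "score", label = "label",
                                    n_boot = 2000, alpha = 0.05, seed = 1) {
  if (n_boot < 200) stop("n_boot must be at least 200")
  scores <- data[[score]]
  labels <- data[[label]]
  .check_scored(scores, labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  point <- .auc_mw(scores, labels)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bp <- pos[sample.int(length(pos), replace = TRUE)]
      bn <- neg[sample.int(length(neg), replace = TRUE)]
      .auc_mw(c(bp, bn), rep(c(1, 0), c(length(bp), length(bn))))
    }, numeric(1))
  })
  ci <- unname(quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  tibble::tibble(
    auc = point,
    ci_low = min(ci[1], point),
    ci_high = max(ci[2], point),
    method = "stratified_bootstrap",
    n_boot = as.integer(n_boot),
    alpha = alpha
  )
}

# DeLong asymptotic CI (used as a cross-check and for fast summaries)
delong_ci <- function(scores, labels, alpha = 0.05) {
  p <- .placements(scores, labels)
  auc <- mean(p$v_pos)
  se <- sqrt(var(p$v_pos) / length(p$v_pos) + var(p$v_neg) / length(p$v_neg))
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(
    auc = auc,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    method = "delong",
    n_boot = NA_integer_,
    alpha = alpha
  )
}
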