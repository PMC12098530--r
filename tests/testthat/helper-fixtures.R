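# small spec tables and cohorts used across tests; everything is generated
# in code, seeded, and cheap

toy_specs <- function(prevalence, beta, names = NULL,
                      category = "indicator") {
  p <- length(prevalence)
  if (is.null(names)) names <- sprintf("X%02d", seq_len(p))
  tibble::tibble(
    name = names,
    label = names,
    category = rep_len(category, p),
    prevalence = prevalence,
    beta = beta
  )
}

# cohort with a handful of strong predictors (heterogeneous effects and
# prevalences, so risk levels are distinguishable) and the rest pure noise
signal_noise_cohort <- function(n, n_signal = 3, n_noise = 5, seed = 1) {
  specs <- toy_specs(
    prevalence = c(rep_len(c(0.2, 0.3, 0.4), n_signal),
                   rep(0.3, n_noise)),
    beta = c(rep_len(log(c(8, 5, 3)), n_signal), rep(0, n_noise)),
    names = c(sprintf("Sig%d", seq_len(n_signal)),
              sprintf("Noise%d", seq_len(n_noise)))
  )
  generate_cohort(specs, n = n, target_prevalence = 0.3, seed = seed)
}

# scored-outcome tibble with controllable signal
scored_fixture <- function(n = 60, prev = 1 / 3, signal = 1, seed = 1) {
  withr::with_seed(seed, {
    label <- rbinom(n, 1, prev)
    if (sum(label) == 0) label[1] <- 1
    if (sum(label) == n) label[1] <- 0
    tibble::tibble(score = signal * label + rnorm(n), label = label)
  })
}

# independent trapezoidal AUC: area under the empirical ROC curve,
# thresholds swept over unique scores (oracle for the Mann-Whitney identity)
trapezoid_auc <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# independent pair-counting AUC (oracle): fraction of (pos, neg) pairs the
# positive wins, ties half-credited
paircount_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# greedy backward elimination oracle: at each step enumerate every
# single-removal AIC with plain glm() and remove the best, preferring
# removal on ties; independent of the package's fitting path
backward_oracle <- function(data, outcome = "outcome") {
  preds <- setdiff(names(data), c("subject_id", outcome))
  aic_of <- function(set) {
    fml <- stats::reformulate(if (length(set)) set else "1",
                              response = outcome)
    stats::AIC(glm(fml, data = data, family = binomial()))
  }
  current <- preds
  current_aic <- aic_of(current)
  trajectory <- list(list(step = 0L, predictor = NA_character_,
                          aic = current_aic))
  step <- 0L
  repeat {
    if (!length(current)) break
    pool <- sort(current)
    aics <- vapply(pool, function(p) aic_of(setdiff(current, p)),
                   numeric(1))
    best <- which.min(aics)
    if (aics[best] > current_aic + 1e-8) break
    step <- step + 1L
    current <- setdiff(current, pool[best])
    current_aic <- aics[[best]]
    trajectory[[length(trajectory) + 1L]] <-
      list(step = step, predictor = pool[best], aic = current_aic)
  }
  list(retained = current,
       trajectory = dplyr::bind_rows(lapply(trajectory, tibble::as_tibble)))
}
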