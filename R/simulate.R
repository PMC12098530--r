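#' Configuration for the prevalence-threshold simulation study
#'
#' The simulation study asks how raising the prevalence of the predictors
#' changes variable-selection behaviour. Cohorts are generated at four
#' prevalence thresholds — the original spec prevalences, then floors of
#' 10%, 20% and 30% — and each cohort is analysed by a single random forest
#' (importance ranks + K-fold CV AUC) and by stepwise regression (retained
#' set + K-fold CV AUC of the retained model). Betas are held fixed across
#' thresholds so only prevalence varies; by default the intercept is
#' recalibrated per threshold to hold the outcome prevalence at its target,
#' so the AUC trend is not confounded by a drifting outcome rate.
#'
#' Two scales are provided. `"full"` is the definitive design: 1000 datasets
#' per threshold, n = 3473, 10,000 trees, 10 folds. `"desk"` is a
#' single-machine design for testing and exploration: 20 datasets per
#' threshold, n = 500, 300 trees, 5 folds.
#'
#' @param scale `"desk"` or `"full"`; sets defaults which the other
#'   arguments override.
#' @param thresholds Prevalence floors; `0` means the original prevalences.
#' @param n_datasets Datasets per threshold.
#' @param specs Predictor specification tibble.
#' @param n Subjects per cohort.
#' @param target_outcome_prevalence Outcome prevalence the intercept is
#'   calibrated to.
#' @param mtry,n_trees,k_folds Forest and cross-validation settings (a
#'   single forest per dataset).
#' @param swr_direction `"backward"` (default) or `"forward"`.
#' @param recalibrate_intercept Recalibrate the intercept at each threshold
#'   (default `TRUE`); `FALSE` keeps the original-threshold intercept.
#' @param master_seed Master seed; every dataset derives its own seed, and
#'   the RF and SWR arms consume identical cohorts.
#' @param checkpoint_dir Optional directory for per-dataset checkpoint
#'   files; reruns skip completed datasets.
#' @return A list of class `lpp_sim_config`.
#' @export
simulation_config <- function(scale = c("desk", "full"),
                              thresholds = c(0, 0.10, 0.20, 0.30),
                              n_datasets = NULL, specs = NULL, n = NULL,
                              target_outcome_prevalence = 0.151,
                              mtry = 3, n_trees = NULL, k_folds = NULL,
                              swr_direction = c("backward", "forward"),
                              recalibrate_intercept = TRUE,
                              master_seed = 1, checkpoint_dir = NULL) {
  scale <- match.arg(scale)
  defaults <- if (scale == "desk") {
    list(n_datasets = 20L, n = 500L, n_trees = 300L, k_folds = 5L)
  } else {
    list(n_datasets = 1000L, n = 3473L, n_trees = 10000L, k_folds = 10L)
  }
  cfg <- list(
    scale = scale,
    thresholds = thresholds,
    n_datasets = as.integer(n_datasets %||% defaults$n_datasets),
    specs = validate_predictor_specs(specs %||% default_predictor_specs()),
    n = as.integer(n %||% defaults$n),
    target_outcome_prevalence = target_outcome_prevalence,
    mtry = mtry,
    n_trees = as.integer(n_trees %||% defaults$n_trees),
    k_folds = as.integer(k_folds %||% defaults$k_folds),
    swr_direction = match.arg(swr_direction),
    recalibrate_intercept = recalibrate_intercept,
    master_seed = as.integer(master_seed),
    checkpoint_dir = checkpoint_dir
  )
  if (cfg$scale == "desk" &&
      (cfg$n_datasets > 50L || cfg$n_trees > 500L)) {
    stop("desk scale caps n_datasets at 50 and n_trees at 500")
  }
  structure(cfg, class = "lpp_sim_config")
}

threshold_label <- function(floor) {
  ifelse(floor == 0, "original", paste0(floor * 100, "%"))
}

threshold_labels <- function(cfg) threshold_label(cfg$thresholds)

# per-threshold generating specs and intercept (calibrated once)
.threshold_setup <- function(cfg, t_idx) {
  floored <- apply_prevalence_floor(cfg$specs, cfg$thresholds[t_idx])
  intercept <- if (cfg$recalibrate_intercept || t_idx == 1L) {
    calibrate_intercept(floored, cfg$target_outcome_prevalence,
                        seed = derive_seed(cfg$master_seed, 9000L + t_idx))
  } else {
    calibrate_intercept(apply_prevalence_floor(cfg$specs, cfg$thresholds[1]),
                        cfg$target_outcome_prevalence,
                        seed = derive_seed(cfg$master_seed, 9001L))
  }
  list(specs = floored, intercept = intercept)
}

# shared per-dataset cohort: identical for the RF and SWR arms
.sim_cohort <- function(cfg, setup, t_idx, d) {
  generate_cohort_safe(setup$specs, cfg$n, setup$intercept,
                       derive_seed(cfg$master_seed, t_idx, d))
}

.checkpoint_path <- function(cfg, arm, t_idx, d) {
  if (is.null(cfg$checkpoint_dir)) return(NULL)
  dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$checkpoint_dir,
            sprintf("%s_t%d_d%04d.rds", arm, t_idx, d))
}

.with_checkpoint <- function(path, expr) {
  if (!is.null(path) && file.exists(path)) return(readRDS(path))
  value <- force(expr)
  if (!is.null(path)) saveRDS(value, path)
  value
}

#' Random-forest arm of the simulation study
#'
#' Per threshold and dataset: generate the cohort, train one forest on the
#' full cohort to obtain unscaled permutation-importance ranks (1 = highest
#' importance, ties lexicographic), and compute the pooled out-of-fold CV
#' AUC of an all-predictor forest. Rank distributions and per-threshold AUC
#' mean/SD are aggregated over datasets.
#'
#' @param config An [simulation_config()] object.
#' @return An object of class `lpp_rf_simulation`: list with `rank_counts`
#'   (tibble: `predictor`, `threshold`, `rank`, `n`), `aucs` (tibble:
#'   `threshold`, `dataset`, `auc`), `auc_summary` (tibble: `threshold`,
#'   `mean_auc`, `sd_auc`), `n_regenerated`, `config`.
#' @export
run_rf_simulation <- function(config) {
  stopifnot(inherits(config, "lpp_sim_config"))
  labels <- threshold_labels(config)
  ranks <- list()
  aucs <- list()
  n_regen <- 0L
  for (t_idx in seq_along(config$thresholds)) {
    setup <- .threshold_setup(config, t_idx)
    for (d in seq_len(config$n_datasets)) {
      res <- .with_checkpoint(
        .checkpoint_path(config, "rf", t_idx, d),
        {
          gen <- .sim_cohort(config, setup, t_idx, d)
          cohort <- gen$cohort
          preds <- predictor_columns(cohort)
          seed_d <- derive_seed(config$master_seed, 100L + t_idx, d)
          imp <- withr::with_seed(derive_seed(seed_d, 1L), {
            rf <- randomForest::randomForest(
              as.matrix(cohort[preds]),
              factor(cohort$outcome, levels = c(0, 1)),
              ntree = config$n_trees, mtry = config$mtry, importance = TRUE
            )
            randomForest::importance(rf, type = 1, scale = FALSE)[preds, 1]
          })
          ord <- order(-imp, preds)
          rk <- integer(length(preds))
          rk[ord] <- seq_along(preds)
          cv <- cv_forest_predictions(cohort, preds, config$mtry,
                                      config$n_trees, config$k_folds,
                                      derive_seed(seed_d, 2L))
          list(ranks = setNames(rk, preds),
               auc = .auc_mw(cv$score, cv$label),
               regenerated = gen$regenerated)
        }
      )
      n_regen <- n_regen + res$regenerated
      ranks[[length(ranks) + 1L]] <- tibble::tibble(
        predictor = names(res$ranks), threshold = labels[t_idx],
        rank = unname(res$ranks)
      )
      aucs[[length(aucs) + 1L]] <- tibble::tibble(
        threshold = labels[t_idx], dataset = d, auc = res$auc
      )
    }
  }
  rank_long <- dplyr::bind_rows(ranks)
  rank_counts <- dplyr::count(rank_long, .data$predictor, .data$threshold,
                              .data$rank, name = "n")
  aucs <- dplyr::bind_rows(aucs)
  structure(
    list(
      rank_counts = rank_counts,
      aucs = aucs,
      auc_summary = .auc_summary(aucs, labels),
      n_regenerated = n_regen,
      config = config
    ),
    class = "lpp_rf_simulation"
  )
}

#' Stepwise-regression arm of the simulation study
#'
#' Per threshold and dataset (the same cohorts as the RF arm): run the
#' configured stepwise direction, record the retained set, and score the
#' retained model by pooled out-of-fold CV AUC. Retention counts and
#' per-threshold AUC mean/SD are aggregated.
#'
#' @param config An [simulation_config()] object.
#' @return An object of class `lpp_swr_simulation`: list with `retention`
#'   (tibble: `predictor`, `threshold`, `n_retained`), `aucs`,
#'   `auc_summary`, `n_regenerated`, `config`.
#' @export
run_swr_simulation <- function(config) {
  stopifnot(inherits(config, "lpp_sim_config"))
  labels <- threshold_labels(config)
  retained <- list()
  aucs <- list()
  n_regen <- 0L
  for (t_idx in seq_along(config$thresholds)) {
    setup <- .threshold_setup(config, t_idx)
    for (d in seq_len(config$n_datasets)) {
      res <- .with_checkpoint(
        .checkpoint_path(config, "swr", t_idx, d),
        {
          gen <- .sim_cohort(config, setup, t_idx, d)
          cohort <- gen$cohort
          sw <- if (config$swr_direction == "backward") {
            backward_stepwise(cohort, cv = FALSE)
          } else {
            forward_stepwise(cohort, cv = FALSE)
          }
          seed_d <- derive_seed(config$master_seed, 200L + t_idx, d)
          auc <- if (length(sw$retained)) {
            cv_logistic_auc(cohort, sw$retained, k_folds = config$k_folds,
                            seed = seed_d, n_boot = 0)$auc
          } else {
            0.5 # empty model scores all subjects equally
          }
          list(retained = sw$retained, auc = auc,
               regenerated = gen$regenerated)
        }
      )
      n_regen <- n_regen + res$regenerated
      retained[[length(retained) + 1L]] <- tibble::tibble(
        predictor = res$retained, threshold = labels[t_idx]
      )
      aucs[[length(aucs) + 1L]] <- tibble::tibble(
        threshold = labels[t_idx], dataset = d, auc = res$auc
      )
    }
  }
  all_preds <- config$specs$name
  counts <- dplyr::count(dplyr::bind_rows(retained), .data$predictor,
                         .data$threshold, name = "n_retained")
  # complete the grid so never-retained predictors appear with count 0
  grid <- tidyr::expand_grid(predictor = all_preds, threshold = labels)
  retention <- dplyr::left_join(grid, counts,
                                by = c("predictor", "threshold"))
  retention$n_retained[is.na(retention$n_retained)] <- 0L
  aucs <- dplyr::bind_rows(aucs)
  structure(
    list(
      retention = retention,
      aucs = aucs,
      auc_summary = .auc_summary(aucs, labels),
      n_regenerated = n_regen,
      config = config
    ),
    class = "lpp_swr_simulation"
  )
}

.auc_summary <- function(aucs, labels) {
  out <- dplyr::summarise(
    dplyr::group_by(aucs, .data$threshold),
    mean_auc = mean(.data$auc), sd_auc = sd(.data$auc), .groups = "drop"
  )
  out$threshold <- factor(out$threshold, levels = labels)
  dplyr::arrange(out, .data$threshold)
}

#' Shift in importance-rank distributions between two thresholds
#'
#' Summarises, per predictor, how the empirical distribution of importance
#' ranks moved between two prevalence thresholds: the median-rank shift
#' (negative = moved toward rank 1, i.e. more important) and the change in
#' IQR (negative = less variability).
#'
#' @param rank_counts The `rank_counts` tibble of an `lpp_rf_simulation`
#'   (or a compatible tibble with `predictor`, `threshold`, `rank`, `n`).
#' @param from,to Threshold labels to compare (e.g. `"original"`, `"30%"`).
#' @return A tibble: `predictor`, `median_from`, `median_to`, `shift`,
#'   `iqr_from`, `iqr_to`, `iqr_change`.
#' @export
summarize_rank_shift <- function(rank_counts, from = "original",
                                 to = "30%") {
  present <- unique(rank_counts$threshold)
  if (!all(c(from, to) %in% present)) {
    stop("thresholds not present in rank_counts: ",
         paste(setdiff(c(from, to), present), collapse = ", "))
  }
  one <- function(thr) {
    d <- rank_counts[rank_counts$threshold == thr, ]
    purrr::map_dfr(split(d, d$predictor), function(g) {
      q <- counts_quantile(g$rank, g$n, c(0.25, 0.5, 0.75))
      tibble::tibble(predictor = g$predictor[1], median = q[2],
                     iqr = q[3] - q[1])
    })
  }
  a <- one(from)
  b <- one(to)
  out <- dplyr::inner_join(a, b, by = "predictor",
                           suffix = c("_from", "_to"))
  dplyr::transmute(
    out,
    predictor = .data$predictor,
    median_from = .data$median_from,
    median_to = .data$median_to,
    shift = .data$median_to - .data$median_from,
    iqr_from = .data$iqr_from,
    iqr_to = .data$iqr_to,
    iqr_change = .data$iqr_to - .data$iqr_from
  )
}
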