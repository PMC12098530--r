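#' Run manifest
#'
#' Every multi-stage run records a manifest — the command, a configuration
#' snapshot, the master seed and derived-seed scheme, software version and
#' timestamps — sufficient to replay the run and reproduce its numeric
#' outputs at the recorded scale.
#'
#' @param command Short string naming the entry point.
#' @param config List of the settings the run used.
#' @param seed Master seed.
#' @param counts Named integer-ish list of per-stage row counts.
#' @return A list of class `lpp_manifest`.
#' @export
run_manifest <- function(command, config, seed, counts = list()) {
  structure(
    list(
      command = command,
      config = config,
      master_seed = seed,
      seed_scheme = seed_scheme_id(),
      package_version = as.character(utils::packageVersion("lppselect")),
      r_version = R.version.string,
      started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      counts = counts
    ),
    class = "lpp_manifest"
  )
}

#' Write a manifest as JSON
#' @param manifest An `lpp_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Head-to-head comparison of forest and stepwise variable selection
#'
#' Runs the complete analysis on one cohort: the forest selection procedure
#' at each requested `mtry`, plus forward and backward AIC stepwise
#' regression, and assembles a side-by-side report — per-method retained
#' sets, how many retained predictors are low-prevalence (empirical cohort
#' prevalence < 10%), cross-validated AUCs with CIs, and the set
#' differences between the best forest model and the backward stepwise
#' model.
#'
#' @param cohort Cohort tibble.
#' @param mtry_values Forest sweep values.
#' @param n_trees,n_repeats,k_folds,alpha,k_min,n_boot Settings passed to
#'   the forest and stepwise stages.
#' @param seed Master seed for the whole comparison.
#' @param lpp_threshold Prevalence below which a predictor counts as
#'   low-prevalence (default 0.10).
#' @return An object of class `lpp_comparison`: list with `summary`
#'   (tibble: `method`, `n_retained`, `n_lpp`, `auc`, `ci_low`, `ci_high`),
#'   `rf_sweep`, `swr` (list `backward`, `forward`), `sets` (retained sets
#'   and their intersection/differences), `lpp_names`, `manifest`.
#' @export
run_full_comparison <- function(cohort, mtry_values = c(3, 6, 16),
                                n_trees = 500, n_repeats = 5, k_folds = 10,
                                alpha = 0.05, k_min = 3, n_boot = 500,
                                seed = 1, lpp_threshold = 0.10) {
  assert_binary_dataset(cohort)
  preds <- predictor_columns(cohort)
  emp_prev <- vapply(cohort[preds], mean, numeric(1))
  lpp_names <- preds[emp_prev < lpp_threshold]

  sweep <- mtry_sweep(cohort, mtry_values, n_trees = n_trees,
                      n_repeats = n_repeats, k_folds = k_folds,
                      alpha = alpha, k_min = k_min, n_boot = n_boot,
                      seed = derive_seed(seed, 1L))
  backward <- backward_stepwise(cohort, k_folds = k_folds,
                                seed = derive_seed(seed, 2L),
                                n_boot = n_boot)
  forward <- forward_stepwise(cohort, k_folds = k_folds,
                              seed = derive_seed(seed, 3L),
                              n_boot = n_boot)

  rf_rows <- purrr::map_dfr(seq_along(mtry_values), function(i) {
    run <- sweep[[i]]
    sel <- run$selection
    retained <- if (is.null(sel)) character(0) else sel$retained
    has_model <- !is.null(sel) && !is.na(sel$chosen_k)
    row <- if (has_model) sel$nested[sel$nested$k == sel$chosen_k, ]
           else NULL
    tibble::tibble(
      method = paste0("rf_mtry", mtry_values[i]),
      n_retained = length(retained),
      n_lpp = length(intersect(retained, lpp_names)),
      auc = if (has_model) row$auc else NA_real_,
      ci_low = if (has_model) row$ci_low else NA_real_,
      ci_high = if (has_model) row$ci_high else NA_real_
    )
  })
  swr_row <- function(sw, name) {
    tibble::tibble(
      method = name,
      n_retained = length(sw$retained),
      n_lpp = length(intersect(sw$retained, lpp_names)),
      auc = if (is.null(sw$cv_auc)) NA_real_ else sw$cv_auc$auc,
      ci_low = if (is.null(sw$cv_auc)) NA_real_ else sw$cv_auc$ci_low,
      ci_high = if (is.null(sw$cv_auc)) NA_real_ else sw$cv_auc$ci_high
    )
  }
  summary <- dplyr::bind_rows(rf_rows, swr_row(backward, "swr_backward"),
                              swr_row(forward, "swr_forward"))

  # best forest model (highest AUC among those with a chosen sub-model)
  rf_ok <- rf_rows[!is.na(rf_rows$auc), ]
  best_rf <- if (nrow(rf_ok)) rf_ok$method[which.max(rf_ok$auc)]
             else NA_character_
  best_rf_set <- if (is.na(best_rf)) character(0) else {
    i <- match(best_rf, paste0("rf_mtry", mtry_values))
    sweep[[i]]$selection$retained
  }
  sets <- list(
    rf_best = best_rf_set,
    rf_best_method = best_rf,
    swr_backward = backward$retained,
    swr_forward = forward$retained,
    intersection = intersect(best_rf_set, backward$retained),
    rf_only = setdiff(best_rf_set, backward$retained),
    swr_only = setdiff(backward$retained, best_rf_set)
  )

  manifest <- run_manifest(
    "run_full_comparison",
    list(mtry_values = mtry_values, n_trees = n_trees,
         n_repeats = n_repeats, k_folds = k_folds, alpha = alpha,
         k_min = k_min, n_boot = n_boot, lpp_threshold = lpp_threshold),
    seed,
    counts = list(n_subjects = nrow(cohort), n_predictors = length(preds),
                  n_lpp = length(lpp_names))
  )

  structure(
    list(summary = summary, rf_sweep = sweep,
         swr = list(backward = backward, forward = forward),
         sets = sets, lpp_names = lpp_names, manifest = manifest),
    class = "lpp_comparison"
  )
}

#' @export
print.lpp_comparison <- function(x, ...) {
  cat("Forest vs stepwise variable selection\n")
  cat("  low-prevalence predictors in cohort:", length(x$lpp_names), "\n\n")
  print(x$summary)
  cat("\nbest forest model:", x$sets$rf_best_method %||% "none", "\n")
  cat("  shared with backward stepwise:", length(x$sets$intersection),
      " forest-only:", length(x$sets$rf_only),
      " stepwise-only:", length(x$sets$swr_only), "\n")
  invisible(x)
}

#' Export a comparison's tables as CSV
#'
#' Writes the summary table, per-mtry importance tables and nested-model
#' tables, and the stepwise odds-ratio tables into a directory, together
#' with the JSON manifest.
#'
#' @param comparison An `lpp_comparison`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(comparison$summary, file.path(dir, "summary.csv"))
  for (nm in names(comparison$rf_sweep)) {
    run <- comparison$rf_sweep[[nm]]
    readr::write_csv(run$importance,
                     file.path(dir, paste0("importance_", nm, ".csv")))
    if (!is.null(run$selection)) {
      readr::write_csv(run$selection$nested,
                       file.path(dir, paste0("nested_", nm, ".csv")))
    }
  }
  for (dirn in c("backward", "forward")) {
    sw <- comparison$swr[[dirn]]
    if (!is.null(sw$final_fit)) {
      readr::write_csv(wald_odds_ratios(sw$final_fit),
                       file.path(dir, paste0("odds_ratios_", dirn, ".csv")))
    }
    readr::write_csv(sw$trajectory,
                     file.path(dir, paste0("trajectory_", dirn, ".csv")))
  }
  write_manifest(comparison$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
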