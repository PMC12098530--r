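#' Plot an averaged importance table
#'
#' Dot-and-whisker plot of mean permutation importance (+/- one SD across
#' forest repeats), ordered by rank.
#'
#' @param object An `lpp_importance` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpp_importance <- function(object, ...) {
  d <- dplyr::mutate(
    tibble::as_tibble(object),
    predictor = stats::reorder(.data$predictor, -.data$rank)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_importance,
                                  y = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_importance - .data$sd_importance,
                   xmax = .data$mean_importance + .data$sd_importance),
      height = 0.25, colour = "grey40"
    ) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = "mean permutation importance (OOB accuracy drop)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sequential selection run
#'
#' Nested-model AUC (with bootstrap CI ribbon) against the number of ranked
#' predictors included, with the full-model AUC as a reference line and the
#' parsimonious model highlighted.
#'
#' @param object An `lpp_rf_selection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpp_rf_selection <- function(object, ...) {
  d <- object$nested
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = object$full_auc$auc, linetype = 2) +
    ggplot2::labs(x = "number of top-ranked predictors",
                  y = "pooled out-of-fold AUC",
                  subtitle = paste0("mtry = ", object$mtry,
                                    "; dashed = full model")) +
    ggplot2::theme_minimal()
  if (!is.na(object$chosen_k)) {
    p <- p + ggplot2::geom_point(
      data = d[d$k == object$chosen_k, ],
      colour = "red", size = 3, shape = 1, stroke = 1.2
    )
  }
  p
}

#' Plot importance-rank distributions across prevalence thresholds
#'
#' Boxplots of per-dataset importance ranks for each predictor, one colour
#' per prevalence threshold (rank 1 = most important, drawn at the top).
#'
#' @param object An `lpp_rf_simulation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpp_rf_simulation <- function(object, ...) {
  labels <- threshold_labels(object$config)
  d <- tidyr::uncount(object$rank_counts, weights = .data$n)
  d$threshold <- factor(d$threshold, levels = labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor, y = .data$rank,
                                  fill = .data$threshold)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.25) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "importance rank (1 = highest)",
                  fill = "prevalence\nthreshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot retention frequencies across prevalence thresholds
#'
#' Bars of how often each predictor was retained by the stepwise procedure,
#' grouped by prevalence threshold.
#'
#' @param object An `lpp_swr_simulation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpp_swr_simulation <- function(object, ...) {
  labels <- threshold_labels(object$config)
  d <- object$retention
  d$threshold <- factor(d$threshold, levels = labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor,
                                  y = .data$n_retained,
                                  fill = .data$threshold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "datasets in which retained",
                  fill = "prevalence\nthreshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
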