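# ggplot2 views of the main result types.

#' Plot cross-validation fold scores
#'
#' Boxplots of the fold-level scores per metric.
#'
#' @param object A `cv_scores` tibble from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_scores
#' @export
autoplot.cv_scores <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "fold score",
                  title = sprintf("%s, %d reps x %d folds",
                                  attr(object, "family") %||% "classifier",
                                  attr(object, "repetitions") %||% NA,
                                  attr(object, "k") %||% NA)) +
    ggplot2::theme_minimal()
}

#' Plot paired fold-level differences between two arms
#'
#' Histogram of the fold-level differences with the grand mean and the
#' repeated-CV 95% confidence interval.
#'
#' @param object A [paired_cv_difference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paired_cv_difference
#' @export
autoplot.paired_cv_difference <- function(object, ...) {
  ci <- paired_ci95(object)
  ggplot2::ggplot(tibble::tibble(d = as.numeric(object$d)),
                  ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_diff, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = unname(ci), linetype = "dashed") +
    ggplot2::labs(x = sprintf("fold-level %s difference", object$metric),
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an experiment's degradation profile
#'
#' Mean score of each presence/absence arm minus the abundance baseline, by
#' binarization threshold, faceted by rank and classifier.
#'
#' @param object A `pa_experiment` from [run_experiment()].
#' @param metric Metric to display (default `"auc"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pa_experiment
#' @export
autoplot.pa_experiment <- function(object, metric = "auc", ...) {
  s <- dplyr::filter(object$summary, .data$metric == .env$metric)
  base <- dplyr::filter(s, is.na(.data$threshold_percent)) |>
    dplyr::select("dataset", "rank", "classifier", base_mean = "mean")
  arms <- dplyr::filter(s, !is.na(.data$threshold_percent)) |>
    dplyr::inner_join(base, by = c("dataset", "rank", "classifier")) |>
    dplyr::mutate(diff = .data$mean - .data$base_mean)
  ggplot2::ggplot(arms, ggplot2::aes(x = factor(.data$threshold_percent),
                                     y = .data$diff, group = 1)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::facet_grid(rank ~ classifier) +
    ggplot2::labs(x = "binarization threshold (%)",
                  y = sprintf("%s difference vs abundance baseline", metric)) +
    ggplot2::theme_minimal()
}

#' Plot significant-feature counts per testing mode
#'
#' Bars of significant taxa (q below `alpha`) for the abundance and presence
#' testing modes.
#'
#' @param records A tibble of [significant_taxa()] records (both modes bound
#'   together, e.g. `diff_features` of a `pa_experiment`).
#' @param alpha Significance level on q.
#' @return A ggplot object.
#' @export
plot_significant_counts <- function(records, alpha = 0.05) {
  counts <- records |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(n_significant = sum(.data$q < alpha), .groups = "drop")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$mode, y = .data$n_significant)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = sprintf("taxa with q < %g", alpha)) +
    ggplot2::theme_minimal()
}
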