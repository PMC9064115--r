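# Paired comparison of two arms' fold-level AUCs under repeated
# cross-validation: the repeated-CV 95% confidence interval and two-tailed
# t-test with df = k - 1.
#
# With d[j, i] the fold-level difference (arm 1 minus arm 2) in fold i of
# repetition j, sigma_j the SD of row j over the k folds, and
# SE = (1/R) * sum_j sigma_j / sqrt(k):
#   CI95 = mean(d) +/- t_{0.975, k-1} * SE      (t_{0.975, 9} = 2.26 for k = 10)
#   t    = mean(d) / SE, two-tailed p under the t law with df = k - 1.

#' Fold-level differences between two cross-validation arms
#'
#' Joins two long-format score tables on (repetition, fold) for one metric and
#' builds the repetitions-by-folds difference matrix plus its per-repetition
#' standard deviations. Both arms must come from the same split set, so the
#' differences are paired fold by fold.
#'
#' @param scores_a,scores_b `cv_scores` tibbles from [run_cv()] evaluated on
#'   the same `cv_splits`.
#' @param metric Metric to compare (default `"auc"`).
#' @return A list of class `paired_cv_difference`: `d` (R x k matrix),
#'   `rep_sd` (length-R, n-1 divisor), `mean_diff`, `k`, `repetitions`,
#'   `metric`.
#' @export
paired_cv_difference <- function(scores_a, scores_b, metric = "auc") {
  a <- dplyr::filter(tibble::as_tibble(scores_a), .data$metric == .env$metric)
  b <- dplyr::filter(tibble::as_tibble(scores_b), .data$metric == .env$metric)
  if (!nrow(a) || !nrow(b)) stop_input(sprintf("Metric '%s' not found.", metric))
  j <- dplyr::inner_join(a, b, by = c("repetition", "fold"),
                         suffix = c("_a", "_b"))
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b)) {
    stop_input("Arms do not share the same (repetition, fold) grid.")
  }
  wide <- tidyr::pivot_wider(
    dplyr::transmute(j, .data$repetition, .data$fold,
                     d = .data$value_a - .data$value_b),
    names_from = "fold", values_from = "d"
  )
  d <- as.matrix(wide[-1])
  if (anyNA(d)) stop_input("Incomplete difference matrix (missing folds).")
  structure(
    list(
      d = d, rep_sd = apply(d, 1, sd), mean_diff = mean(d),
      k = ncol(d), repetitions = nrow(d), metric = metric
    ),
    class = "paired_cv_difference"
  )
}

# Repetition-averaged standard error: (1/R) * sum_j sigma_j / sqrt(k).
paired_se <- function(diff) mean(diff$rep_sd) / sqrt(diff$k)

#' Repeated-CV 95% confidence interval on a paired AUC difference
#'
#' `mean_diff +/- t_{0.975, k-1} * SE` with the repetition-averaged standard
#' error `SE = (1/R) sum_j sigma_j / sqrt(k)`; for k = 10 folds the multiplier
#' is the 0.975 quantile of the t law at 9 degrees of freedom (2.26).
#'
#' @param diff A [paired_cv_difference()].
#' @return Named numeric vector `c(low, high)`.
#' @export
paired_ci95 <- function(diff) {
  stopifnot(inherits(diff, "paired_cv_difference"))
  se <- paired_se(diff)
  tcrit <- qt(0.975, df = diff$k - 1)
  c(low = diff$mean_diff - tcrit * se, high = diff$mean_diff + tcrit * se)
}

#' Repeated-CV paired t-test on fold-level differences
#'
#' `t = mean_diff / SE` with the same standard error as [paired_ci95()];
#' two-tailed p under the t law with `df = k - 1`. Degenerate spread
#' (`SE = 0`) yields `t = 0, p = 1` when the mean difference is zero, else
#' `p = 0` with `degenerate = TRUE`.
#'
#' @param diff A [paired_cv_difference()].
#' @return A list of class `paired_cv_test`: `mean_diff`, `se`, `ci_low`,
#'   `ci_high`, `t`, `p`, `df`, `degenerate`, `metric`, `k`, `repetitions`.
#' @export
paired_t_test <- function(diff) {
  stopifnot(inherits(diff, "paired_cv_difference"))
  se <- paired_se(diff)
  df <- diff$k - 1
  degenerate <- FALSE
  if (se == 0) {
    if (diff$mean_diff == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(diff$mean_diff) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t_stat <- diff$mean_diff / se
    p <- 2 * pt(-abs(t_stat), df = df)
  }
  ci <- paired_ci95(diff)
  structure(
    list(mean_diff = diff$mean_diff, se = se,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         t = t_stat, p = p, df = df, degenerate = degenerate,
         metric = diff$metric, k = diff$k, repetitions = diff$repetitions),
    class = "paired_cv_test"
  )
}

#' Compare two cross-validation arms on one metric
#'
#' Convenience wrapper: builds the paired fold-level differences and runs the
#' repeated-CV confidence interval and t-test in one call.
#'
#' @inheritParams paired_cv_difference
#' @return A `paired_cv_test` (see [paired_t_test()]).
#' @export
compare_arms <- function(scores_a, scores_b, metric = "auc") {
  paired_t_test(paired_cv_difference(scores_a, scores_b, metric = metric))
}

#' @export
print.paired_cv_test <- function(x, ...) {
  cat(sprintf(
    "Paired repeated-CV comparison (%s, %d reps x %d folds)\n  mean diff %+0.4f  95%% CI [%+0.4f, %+0.4f]\n  t = %0.3f (df = %d), two-tailed p = %0.4g%s\n",
    x$metric, x$repetitions, x$k, x$mean_diff, x$ci_low, x$ci_high,
    x$t, x$df, x$p, if (x$degenerate) "  [degenerate spread]" else ""
  ))
  invisible(x)
}

#' Tidy a paired repeated-CV test
#'
#' @param x A `paired_cv_test`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `statistic`, `p.value`, `parameter`, `metric`.
#' @export
tidy.paired_cv_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_diff, conf.low = x$ci_low, conf.high = x$ci_high,
    statistic = x$t, p.value = x$p, parameter = x$df, metric = x$metric
  )
}

#' @rdname tidy.paired_cv_test
#' @export
glance.paired_cv_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_diff, std.error = x$se, statistic = x$t,
    p.value = x$p, df = x$df, nobs = x$k * x$repetitions,
    degenerate = x$degenerate
  )
}
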