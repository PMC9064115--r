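# End-to-end experiment orchestration: simulate/load -> (aggregate) ->
# degrade -> classify -> paired comparison vs the abundance baseline ->
# differential features -> concordance, all sharing one split set per dataset.

#' Run a full degradation experiment on one cohort
#'
#' Executes the factorial ranks x thresholds x classifiers. For every rank and
#' classifier the abundance profile is the baseline arm; each binarization
#' threshold contributes one presence/absence arm, evaluated on the *same*
#' stratified split set and compared with the baseline through the repeated-CV
#' paired t-test. Differential-feature testing (Mann-Whitney on abundances,
#' Fisher on presences at the first threshold) and the cross-mode concordance
#' summary are computed per rank. Deterministic given `seed`.
#'
#' @param profile A non-binary [profile_table()] (ignored when `spec` given).
#' @param metadata Metadata tibble (`sample_id`, `study_id`, `label`,
#'   `disease`); ignored when `spec` given.
#' @param spec Optional [synthetic_spec()]; when supplied the cohort is
#'   simulated from it.
#' @param ranks Taxonomic ranks to evaluate (subset of
#'   `c("species", "genus", "family", "order")`; non-species ranks require
#'   full lineage names).
#' @param thresholds_percent Binarization thresholds in percent.
#' @param classifiers Classifier families (see [run_cv()]).
#' @param k,repetitions Cross-validation geometry.
#' @param alpha Significance level for differential features.
#' @param seed Integer seed governing splits, models and simulation.
#' @param outdir Optional directory; when given, per-arm score TSVs, the
#'   summary table, differential-feature records and a JSON manifest are
#'   written there.
#'
#' @return A list of class `pa_experiment`: `summary` (long tibble: `dataset`,
#'   `rank`, `threshold_percent` (`NA` = abundance baseline), `classifier`,
#'   `metric`, `mean`, `sd`, `ci_low`, `ci_high`, `p_vs_baseline`), `scores`
#'   (named list of `cv_scores`), `comparisons`, `diff_features`,
#'   `concordance`, `splits`, `config`.
#' @export
run_experiment <- function(profile = NULL, metadata = NULL, spec = NULL,
                           ranks = "species",
                           thresholds_percent = c(0, 1e-4, 1e-3, 1e-2, 0.1),
                           classifiers = "rf",
                           k = 10, repetitions = 20, alpha = 0.05, seed = 1,
                           outdir = NULL) {
  ranks <- match.arg(ranks, c("species", "genus", "family", "order"),
                     several.ok = TRUE)
  classifiers <- match.arg(classifiers, CLASSIFIER_FAMILIES, several.ok = TRUE)
  if (!is.null(spec)) {
    cohort <- simulate_cohort(spec, seed = derive_seed(seed, "sim"))
    profile <- cohort$profile
    metadata <- cohort$metadata
  }
  if (is.null(profile) || is.null(metadata)) {
    stop_input("Provide either `profile` + `metadata` or a `spec`.")
  }
  check_cohort(profile, metadata)
  dataset <- unique(as.character(metadata$study_id))[1]
  splits <- make_cv_splits(metadata, k = k, repetitions = repetitions,
                           seed = derive_seed(seed, "splits"))

  scores <- list()
  summary_rows <- list()
  comparison_rows <- list()
  diff_rows <- list()
  conc_rows <- list()

  for (rank in ranks) {
    prof_rank <- if (rank == profile_rank(profile)) {
      profile
    } else {
      aggregate_to_rank(profile, rank)
    }
    for (clf in classifiers) {
      base_key <- paste(rank, clf, "abundance", sep = "|")
      base_scores <- run_cv(prof_rank, metadata, splits, family = clf,
                            seed = derive_seed(seed, "arm", base_key))
      scores[[base_key]] <- base_scores
      summary_rows[[base_key]] <- arm_summary(
        base_scores, dataset, rank, NA_real_, clf, p_vs_baseline = NA_real_
      )
      for (t in thresholds_percent) {
        arm_key <- paste(rank, clf, format(t, scientific = FALSE), sep = "|")
        arm_scores <- run_cv(binarize(prof_rank, t), metadata, splits,
                             family = clf,
                             seed = derive_seed(seed, "arm", arm_key))
        scores[[arm_key]] <- arm_scores
        cmp <- purrr::map_dfr(unique(arm_scores$metric), function(met) {
          dplyr::mutate(tidy(compare_arms(arm_scores, base_scores, met)),
                        .before = 1,
                        dataset = dataset, rank = rank,
                        threshold_percent = t, classifier = clf)
        })
        comparison_rows[[arm_key]] <- cmp
        summary_rows[[arm_key]] <- arm_summary(
          arm_scores, dataset, rank, t, clf,
          p_vs_baseline = cmp$p.value[match(unique(arm_scores$metric), cmp$metric)]
        )
      }
    }
    rec_ab <- significant_taxa(prof_rank, metadata, "abundance", alpha = alpha)
    rec_pr <- significant_taxa(prof_rank, metadata, "presence", alpha = alpha,
                               threshold_percent = thresholds_percent[1])
    diff_rows[[rank]] <- dplyr::mutate(dplyr::bind_rows(rec_ab, rec_pr),
                                       dataset = dataset, rank = rank,
                                       .before = 1)
    conc_rows[[rank]] <- dplyr::mutate(concordance(rec_ab, rec_pr, alpha = alpha),
                                       dataset = dataset, rank = rank,
                                       .before = 1)
  }

  result <- structure(
    list(
      summary = dplyr::bind_rows(summary_rows),
      scores = scores,
      comparisons = dplyr::bind_rows(comparison_rows),
      diff_features = dplyr::bind_rows(diff_rows),
      concordance = dplyr::bind_rows(conc_rows),
      splits = splits,
      config = list(
        dataset = dataset, ranks = ranks,
        thresholds_percent = thresholds_percent,
        classifiers = classifiers, k = k, repetitions = repetitions,
        alpha = alpha, seed = seed
      )
    ),
    class = "pa_experiment"
  )
  if (!is.null(outdir)) write_experiment(result, outdir)
  result
}

# Per-arm summary rows: mean and SD over all fold scores, the repeated-CV CI
# around the arm's own mean (same averaged-SE construction as the paired
# comparison), and the paired p versus the abundance baseline.
arm_summary <- function(scores, dataset, rank, threshold, clf, p_vs_baseline) {
  k <- attr(scores, "k")
  tcrit <- qt(0.975, df = k - 1)
  out <- scores |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      se = mean(tapply(.data$value, .data$repetition, sd)) / sqrt(k),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dataset = dataset, rank = rank, threshold_percent = threshold,
      classifier = clf,
      ci_low = mean - tcrit * .data$se, ci_high = mean + tcrit * .data$se,
      .before = 1
    ) |>
    dplyr::select(-"se")
  out$p_vs_baseline <- p_vs_baseline
  dplyr::relocate(out, "metric", "mean", "sd", "ci_low", "ci_high",
                  "p_vs_baseline", .after = "classifier")
}

write_experiment <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$summary, file.path(outdir, "summary.tsv"))
  readr::write_tsv(result$comparisons, file.path(outdir, "comparisons.tsv"))
  readr::write_tsv(result$diff_features, file.path(outdir, "diff_features.tsv"))
  readr::write_tsv(result$concordance, file.path(outdir, "concordance.tsv"))
  for (key in names(result$scores)) {
    fname <- paste0("scores_", gsub("[^A-Za-z0-9._-]", "_", key), ".tsv")
    readr::write_tsv(tibble::as_tibble(result$scores[[key]]),
                     file.path(outdir, fname))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- c(result$config, list(
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("presaboost")),
      files = list.files(outdir)
    ))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(outdir)
}

#' Rank correlation between two metrics across datasets
#'
#' Spearman correlation of per-dataset mean scores for two metrics, e.g. how
#' well AUC and AUPRC rank datasets the same way.
#'
#' @param summary A summary tibble (rows from one or more `pa_experiment`
#'   summaries) with columns `dataset`, `metric`, `mean`.
#' @param metric_a,metric_b Metric names present for every dataset.
#' @return Spearman rank correlation (single number).
#' @export
correlate_metrics <- function(summary, metric_a = "auc", metric_b = "auprc") {
  summary <- tibble::as_tibble(summary)
  per_ds <- summary |>
    dplyr::filter(.data$metric %in% c(metric_a, metric_b)) |>
    dplyr::group_by(.data$dataset, .data$metric) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
  if (nrow(per_ds) < 3) stop_input("Need at least 3 datasets.")
  if (!all(c(metric_a, metric_b) %in% names(per_ds)) ||
      anyNA(per_ds[[metric_a]]) || anyNA(per_ds[[metric_b]])) {
    stop_input("Both metrics must be present for every dataset.")
  }
  cor(per_ds[[metric_a]], per_ds[[metric_b]], method = "spearman")
}
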