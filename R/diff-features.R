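# Differential features: Mann-Whitney U on relative abundances vs Fisher exact
# on presence counts, BH-FDR across taxa, enrichment direction, and the
# cross-mode concordance summary.

#' Two-sided Mann-Whitney U test p-value
#'
#' Exact p by enumeration of rank assignments when the smaller group has at
#' most 8 observations and the data are tie-free; otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param case_values,control_values Numeric vectors, each nonempty.
#' @return Two-sided p-value.
#' @export
mannwhitney_test <- function(case_values, control_values) {
  if (!length(case_values) || !length(control_values)) {
    stop_input("Both groups must be nonempty.")
  }
  all_vals <- c(case_values, control_values)
  if (length(unique(all_vals)) == 1L) return(1)
  ties <- anyDuplicated(all_vals) > 0
  exact <- !ties && min(length(case_values), length(control_values)) <= 8
  p <- suppressWarnings(
    wilcox.test(case_values, control_values, exact = exact,
                correct = TRUE)$p.value
  )
  min(1, p)
}

#' Two-sided Fisher exact test on presence counts
#'
#' p is the total hypergeometric probability of all 2x2 tables with the same
#' margins whose probability does not exceed that of the observed table.
#'
#' @param present_case,present_control Number of samples in which the taxon is
#'   present, per group.
#' @param n_case,n_control Group sizes.
#' @return Two-sided p-value.
#' @export
fisher_presence_test <- function(present_case, n_case, present_control, n_control) {
  ok <- function(x, n) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x == round(x) && x >= 0 && x <= n
  if (!ok(present_case, n_case) || !ok(present_control, n_control) ||
      n_case < 1 || n_control < 1) {
    stop_input("Counts must satisfy 0 <= present <= n for each group.")
  }
  tab <- matrix(c(present_case, n_case - present_case,
                  present_control, n_control - present_control), nrow = 2)
  min(1, fisher.test(tab)$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1,
#' mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop_input("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential-feature testing across all taxa of a cohort
#'
#' One test per taxon: Mann-Whitney U on the relative abundances
#' (`mode = "abundance"`) or Fisher exact on presence counts after internal
#' binarization at `threshold_percent` (`mode = "presence"`), followed by
#' BH-FDR across the taxa of the cohort. Taxa significant at `q < alpha` get
#' an enrichment direction: the group with higher prevalence (presence mode)
#' or higher mean rank (abundance mode). Constant-zero taxa are flagged and
#' assigned p = 1.
#'
#' @param profile A non-binary [profile_table()].
#' @param metadata Metadata tibble with `sample_id` and 0/1 `label`.
#' @param mode `"abundance"` or `"presence"`.
#' @param alpha Significance level on the q-values (default 0.05).
#' @param threshold_percent Binarization threshold for presence mode
#'   (default 0).
#' @return A tibble: `taxon`, `mode`, `p_raw`, `q`, `direction`
#'   (`"case"`, `"control"` or `"none"`), `degenerate`, plus effect summaries
#'   (`prevalence_case`/`prevalence_control` in presence mode,
#'   `mean_rank_case`/`mean_rank_control` in abundance mode).
#' @export
significant_taxa <- function(profile, metadata, mode = c("abundance", "presence"),
                             alpha = 0.05, threshold_percent = 0) {
  mode <- match.arg(mode)
  labels <- check_cohort(profile, metadata)
  m <- profile_matrix(profile)
  is_case <- labels == 1L
  n_case <- sum(is_case); n_control <- sum(!is_case)

  if (mode == "presence") {
    b <- profile_matrix(binarize(profile, threshold_percent))
    pres_case <- colSums(b[is_case, , drop = FALSE])
    pres_control <- colSums(b[!is_case, , drop = FALSE])
    degenerate <- pres_case + pres_control == 0
    p_raw <- vapply(seq_len(ncol(b)), function(i) {
      if (degenerate[i]) return(1)
      fisher_presence_test(pres_case[i], n_case, pres_control[i], n_control)
    }, numeric(1))
    eff <- tibble::tibble(prevalence_case = pres_case / n_case,
                          prevalence_control = pres_control / n_control)
    dir_case <- eff$prevalence_case > eff$prevalence_control
  } else {
    degenerate <- colSums(m != 0) == 0
    stats <- vapply(seq_len(ncol(m)), function(i) {
      if (degenerate[i]) return(c(1, 0, 0))
      r <- rank(m[, i], ties.method = "average")
      c(mannwhitney_test(m[is_case, i], m[!is_case, i]),
        mean(r[is_case]), mean(r[!is_case]))
    }, numeric(3))
    p_raw <- stats[1, ]
    eff <- tibble::tibble(mean_rank_case = stats[2, ],
                          mean_rank_control = stats[3, ])
    dir_case <- eff$mean_rank_case > eff$mean_rank_control
  }

  q <- bh_fdr(p_raw)
  direction <- dplyr::if_else(q < alpha & !degenerate,
                              dplyr::if_else(dir_case, "case", "control"),
                              "none")
  dplyr::bind_cols(
    tibble::tibble(taxon = colnames(m), mode = mode, p_raw = p_raw, q = q,
                   direction = direction, degenerate = degenerate),
    eff
  )
}

#' Concordance between abundance-mode and presence-mode feature calls
#'
#' Summarizes how well the two testing modes agree over one taxon universe:
#' the fraction of taxa significant in both modes among those significant in
#' at least one, the fraction of direction conflicts among taxa significant in
#' at least one mode (a conflict needs both directions assigned), and the
#' Spearman correlation of `-log10 p` across taxa significant in at least one
#' mode.
#'
#' @param records_abundance,records_presence Tibbles from [significant_taxa()]
#'   over the same taxa.
#' @param alpha Significance level on q (default 0.05).
#' @return A one-row tibble: `n_sig_abundance`, `n_sig_presence`, `n_either`,
#'   `n_both`, `shared_fraction`, `direction_discrepancy_fraction`,
#'   `p_value_correlation`.
#' @export
concordance <- function(records_abundance, records_presence, alpha = 0.05) {
  a <- tibble::as_tibble(records_abundance)
  b <- tibble::as_tibble(records_presence)
  if (!setequal(a$taxon, b$taxon)) {
    stop_input("The two record sets must cover the same taxa.")
  }
  b <- b[match(a$taxon, b$taxon), ]
  sig_a <- a$q < alpha
  sig_b <- b$q < alpha
  either <- sig_a | sig_b
  both <- sig_a & sig_b
  conflict <- both & a$direction != "none" & b$direction != "none" &
    a$direction != b$direction
  pcor <- if (sum(either) >= 3) {
    cor(-log10(pmax(a$p_raw[either], 1e-300)),
        -log10(pmax(b$p_raw[either], 1e-300)), method = "spearman")
  } else {
    NA_real_
  }
  tibble::tibble(
    n_sig_abundance = sum(sig_a), n_sig_presence = sum(sig_b),
    n_either = sum(either), n_both = sum(both),
    shared_fraction = if (any(either)) sum(both) / sum(either) else NA_real_,
    direction_discrepancy_fraction =
      if (any(either)) sum(conflict) / sum(either) else NA_real_,
    p_value_correlation = pcor
  )
}

#' Fraction of diseases in which each taxon is ever significant
#'
#' A taxon scores a hit for a disease when it is significant in at least one
#' dataset of that disease; the per-taxon fraction is hits divided by the
#' number of diseases.
#'
#' @param records A tibble with columns `disease`, `dataset`, `taxon`,
#'   `significant` (logical).
#' @return A tibble `taxon`, `n_diseases`, `fraction`, sorted by decreasing
#'   fraction.
#' @export
per_disease_aggregation <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("disease", "dataset", "taxon", "significant")
  if (!all(need %in% names(records))) {
    stop_input(sprintf("`records` needs columns: %s", paste(need, collapse = ", ")))
  }
  n_diseases <- dplyr::n_distinct(records$disease)
  records |>
    dplyr::group_by(.data$taxon, .data$disease) |>
    dplyr::summarise(hit = any(.data$significant), .groups = "drop") |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_diseases = n_diseases,
      fraction = sum(.data$hit) / n_diseases,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$taxon)
}
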