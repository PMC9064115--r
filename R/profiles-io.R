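# Reading, writing, normalising and rank-aggregating taxonomic profiles.

#' Read a MetaPhlAn-style merged abundance table
#'
#' Reads a tab-separated merged abundance table whose first column holds
#' pipe-delimited, rank-prefixed lineage strings and whose remaining columns are
#' samples with values in percent. Only rows whose deepest populated rank
#' equals `rank` are retained (so genus-level rows are never double-counted
#' with their species, and strain-level rows are excluded). Values are divided
#' by 100 into fractions.
#'
#' Profiles are expected to sum to 100% per sample. When species rows leave
#' unclassified mass behind, row sums fall short of 1; by default this is
#' reported as a warning and the mass is left as-is, while `renormalize = TRUE`
#' restores closure explicitly.
#'
#' @param path Path to the TSV file.
#' @param rank Rank to extract (default `"species"`).
#' @param renormalize Restore per-sample closure to 1 (default `FALSE`).
#' @param tol Closure tolerance on row sums (default `1e-6`).
#'
#' @return A [profile_table()] with samples as rows and taxa as columns.
#' @export
read_metaphlan_table <- function(path, rank = "species", renormalize = FALSE,
                                 tol = 1e-6) {
  rank <- match.arg(rank, names(RANK_PREFIXES))
  raw <- readr::read_tsv(path, comment = "#", col_names = TRUE,
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2L) stop_input("Expected a lineage column plus sample columns.")
  sample_cols <- names(raw)[-1]
  if (anyDuplicated(sample_cols)) {
    stop_input(sprintf(
      "Duplicate sample column(s): %s",
      paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", ")
    ))
  }
  lineages <- as.character(raw[[1]])
  vals <- as.matrix(raw[-1])
  if (!is.numeric(vals)) stop_input("Sample columns must be numeric percentages.")
  if (any(vals < 0)) {
    bad <- lineages[which(rowSums(vals < 0) > 0)[1]]
    stop_input(sprintf("Negative abundance in row '%s'.", bad))
  }
  deep <- deepest_rank(lineages)
  if (anyNA(deep)) {
    stop_input(sprintf(
      "Malformed lineage string in row '%s'.", lineages[which(is.na(deep))[1]]
    ))
  }
  keep <- deep == rank
  if (!any(keep)) stop_input(sprintf("No rows at rank '%s'.", rank))
  frac <- t(vals[keep, , drop = FALSE]) / 100
  colnames(frac) <- lineages[keep]
  out <- tibble::as_tibble(frac)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_cols), out)
  prof <- profile_table(out, rank = rank, binary = FALSE)
  sums <- rowSums(frac)
  if (any(abs(sums - 1) > tol)) {
    if (renormalize) {
      prof <- renormalize(prof)
    } else {
      warn(sprintf(
        "%d sample(s) do not sum to 1 (min %.4g, max %.4g); unclassified mass left in place. Use renormalize = TRUE to restore closure.",
        sum(abs(sums - 1) > tol), min(sums), max(sums)
      ))
    }
  }
  prof
}

#' Write a profile table in MetaPhlAn merged-abundance layout
#'
#' Taxa as rows (lineage strings in the first column), samples as columns,
#' values in percent, full double precision.
#'
#' @param profile A [profile_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metaphlan_table <- function(profile, path) {
  m <- t(profile_matrix(profile)) * 100
  out <- dplyr::bind_cols(
    tibble::tibble(clade_name = rownames(m)),
    tibble::as_tibble(m)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write the canonical profile TSV
#'
#' The canonical on-disk layout used between pipeline stages: samples as rows
#' (first column `sample_id`), taxa as columns, fractional values. The
#' round-trip through [write_profile_table()] and [read_profile_table()]
#' preserves values exactly.
#'
#' @param path Path to a TSV file.
#' @param rank Rank recorded for the taxa.
#' @param binary Whether the stored values are presence/absence indicators.
#' @return A [profile_table()].
#' @export
read_profile_table <- function(path, rank = "species", binary = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  names(raw)[1] <- "sample_id"
  for (j in seq_along(raw)[-1]) raw[[j]] <- as.numeric(raw[[j]])
  profile_table(tibble::as_tibble(raw), rank = rank, binary = binary)
}

#' @rdname read_profile_table
#' @param profile A [profile_table()].
#' @export
write_profile_table <- function(profile, path) {
  # %.17g + strtod on re-read round-trips doubles exactly
  out <- as.data.frame(profile)
  for (j in seq_along(out)[-1]) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `study_id`, `label`, `disease`.
#' Labels are coerced to integers with control = 0 and case = 1; the strings
#' `"control"`/`"case"` are accepted.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with columns `sample_id`, `study_id`, `label`, `disease`.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "study_id", "label", "disease")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop_input(sprintf("Metadata misses column(s): %s", paste(miss, collapse = ", ")))
  }
  md$sample_id <- as.character(md$sample_id)
  if (is.character(md$label)) {
    md$label <- dplyr::case_match(tolower(md$label),
                                  "control" ~ 0L, "case" ~ 1L)
  }
  md$label <- as.integer(md$label)
  if (anyNA(md$label) || !all(md$label %in% c(0L, 1L))) {
    stop_input("`label` must be 0/control or 1/case.")
  }
  tibble::as_tibble(md[need])
}

# Check a (profile, metadata) pair: aligned ids, both classes present.
check_cohort <- function(profile, metadata) {
  if (!setequal(profile$sample_id, metadata$sample_id)) {
    stop_input("Profile and metadata sample ids do not match.")
  }
  labels <- metadata$label[match(profile$sample_id, metadata$sample_id)]
  if (length(unique(labels)) < 2L) {
    stop_input("Both classes (case and control) must be present.")
  }
  labels
}

#' Restore compositional closure of a profile table
#'
#' Divides each sample's abundances by their sum so rows sum to 1. Idempotent
#' on already-closed tables.
#'
#' @param profile A non-binary [profile_table()].
#' @return The renormalized profile table.
#' @export
renormalize <- function(profile) {
  if (profile_is_binary(profile)) {
    stop_input("Cannot renormalize a binary (presence/absence) profile.")
  }
  m <- profile_matrix(profile)
  sums <- rowSums(m)
  if (any(sums <= 0)) {
    stop_input(sprintf(
      "Zero-sum sample(s): %s",
      paste(rownames(m)[sums <= 0], collapse = ", ")
    ))
  }
  res <- dplyr::bind_cols(
    tibble::tibble(sample_id = profile$sample_id),
    tibble::as_tibble(m / sums)
  )
  as_profile(res, rank = profile_rank(profile), binary = FALSE)
}

#' Aggregate a species-level profile to a coarser taxonomic rank
#'
#' Sums the abundances of species sharing the same ancestor at `rank`. Mass is
#' conserved: per-sample row sums are preserved to machine precision, so an
#' input that sums to 1 stays closed.
#'
#' @param profile A non-binary species-level [profile_table()] with full
#'   lineage column names.
#' @param rank Target rank: `"genus"`, `"family"` or `"order"`.
#' @return A [profile_table()] at the requested rank.
#' @export
aggregate_to_rank <- function(profile, rank = c("genus", "family", "order")) {
  rank <- match.arg(rank)
  if (profile_is_binary(profile)) {
    stop_input("Aggregate relative abundances before binarizing, not after.")
  }
  taxa <- profile_taxa(profile)
  anc <- vapply(taxa, truncate_lineage, character(1), rank = rank)
  if (anyNA(anc)) {
    stop_input(sprintf(
      "Taxa lacking a %s ancestor: %s", rank,
      paste(taxa[is.na(anc)], collapse = ", ")
    ))
  }
  m <- profile_matrix(profile)
  groups <- unique(anc)
  agg <- vapply(groups, function(g) {
    rowSums(m[, anc == g, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(NULL, groups))
  res <- dplyr::bind_cols(
    tibble::tibble(sample_id = profile$sample_id),
    tibble::as_tibble(agg)
  )
  as_profile(res, rank = rank, binary = FALSE)
}

#' Preprocess a 16S OTU count table into genus-level relative abundances
#'
#' Applies the standard compendium filters in order: (1) samples with fewer
#' than `min_sample_reads` total reads are discarded; (2) on the surviving
#' samples, OTUs with fewer than `min_otu_reads` total reads or present
#' (count > 0) in less than `min_prevalence_fraction` of samples are removed;
#' (3) counts are converted to per-sample relative abundance; (4) OTUs
#' un-annotated at genus level are dropped and the remainder collapsed to genus
#' by summing relative abundances. All boundaries are strict ("fewer than"):
#' a sample with exactly `min_sample_reads` reads survives.
#'
#' @param counts A data frame: first column `sample_id`, remaining columns
#'   nonnegative integer OTU counts.
#' @param genus_map A data frame with columns `otu_id` and `genus`; `NA` or
#'   empty genus marks an unannotated OTU.
#' @param min_sample_reads Minimum per-sample total reads (default 100).
#' @param min_otu_reads Minimum per-OTU total reads (default 10).
#' @param min_prevalence_fraction Minimum fraction of samples in which an OTU
#'   must be present (default 0.01).
#' @return A genus-level [profile_table()] (taxa named `g__<genus>`).
#' @export
preprocess_16s <- function(counts, genus_map, min_sample_reads = 100,
                           min_otu_reads = 10, min_prevalence_fraction = 0.01) {
  counts <- tibble::as_tibble(counts)
  if (!"sample_id" %in% names(counts)) stop_input("`counts` needs a `sample_id` column.")
  m <- as.matrix(counts[setdiff(names(counts), "sample_id")])
  rownames(m) <- as.character(counts$sample_id)
  if (any(m < 0) || any(m != round(m))) {
    stop_input("OTU counts must be nonnegative integers.")
  }
  keep_s <- rowSums(m) >= min_sample_reads
  if (!any(keep_s)) stop_input("All samples removed by the read-count filter.")
  m <- m[keep_s, , drop = FALSE]

  otu_reads <- colSums(m)
  otu_prev <- colMeans(m > 0)
  keep_o <- otu_reads >= min_otu_reads & otu_prev >= min_prevalence_fraction
  if (!any(keep_o)) stop_input("All OTUs removed by the OTU filters.")
  m <- m[, keep_o, drop = FALSE]

  rel <- m / rowSums(m)

  gm <- tibble::as_tibble(genus_map)
  genus <- gm$genus[match(colnames(rel), gm$otu_id)]
  annotated <- !is.na(genus) & nzchar(genus)
  if (!any(annotated)) stop_input("No OTU is annotated at genus level.")
  rel <- rel[, annotated, drop = FALSE]
  genus <- genus[annotated]

  groups <- unique(genus)
  agg <- vapply(groups, function(g) {
    rowSums(rel[, genus == g, drop = FALSE])
  }, numeric(nrow(rel)))
  if (nrow(rel) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(NULL, groups))
  colnames(agg) <- paste0("g__", groups)
  res <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(agg)
  )
  as_profile(res, rank = "genus", binary = FALSE)
}
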