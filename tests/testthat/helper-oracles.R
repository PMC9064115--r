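# Independent oracles used to verify the package's statistics, and small
# fixture builders. Every oracle here is a literal implementation of the
# defining formula, kept deliberately separate from the package's code paths.

# AUC by exhaustive case/control pair counting.
brute_force_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cs) * length(ct))
}

# Exact two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled tie-free values to the case group.
enum_mwu_p <- function(case_values, control_values) {
  pooled <- c(case_values, control_values)
  n1 <- length(case_values)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(control_values) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all tables
# with the observed margins.
enum_fisher_p <- function(a, n1, b, n2) {
  k <- a + b
  xs <- max(0, k - n2):min(n1, k)
  probs <- stats::dhyper(xs, n1, n2, k)
  p_obs <- stats::dhyper(a, n1, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Literal Benjamini-Hochberg step-up.
literal_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Fixture: profile table from a plain matrix (rows = samples).
make_profile <- function(m, taxa = NULL, rank = "species", binary = FALSE) {
  taxa <- taxa %||% sprintf("s__t%02d", seq_len(ncol(m)))
  colnames(m) <- taxa
  df <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  )
  profile_table(df, rank = rank, binary = binary)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Fixture: full nested lineages, one genus per species, two genera per family.
synthetic_lineages_for_test <- function(n) {
  i <- seq_len(n)
  fa <- ceiling(i / 2); or <- ceiling(fa / 2); cl <- ceiling(or / 2)
  sprintf(
    "k__Bacteria|p__P01|c__C%02d|o__O%02d|f__F%02d|g__Genus_%03d|s__Species_%03d",
    cl, or, fa, i, i
  )
}

# Fixture: metadata for a profile with the first n_case samples as cases.
make_metadata <- function(profile, n_case) {
  n <- nrow(profile)
  tibble::tibble(
    sample_id = profile$sample_id,
    study_id = "T01",
    label = rep(c(1L, 0L), c(n_case, n - n_case)),
    disease = "test"
  )
}

# Fixture: MetaPhlAn-style merged table text with species and higher-rank
# rows, values in percent. Returns the temp file path.
write_metaphlan_fixture <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    "clade_name\tSA\tSB\tSC",
    "k__Bacteria\t100\t100\t100",
    "k__Bacteria|p__Firmicutes\t80\t65\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia\t80\t65\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales\t80\t65\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Lachnospiraceae\t80\t65\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Lachnospiraceae|g__Roseburia\t80\t65\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Lachnospiraceae|g__Roseburia|s__Roseburia_faecis\t50\t40\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Lachnospiraceae|g__Roseburia|s__Roseburia_faecis|t__SGB001\t50\t40\t100",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Lachnospiraceae|g__Roseburia|s__Roseburia_intestinalis\t30\t25\t0",
    "k__Bacteria|p__Bacteroidota\t20\t35\t0",
    "k__Bacteria|p__Bacteroidota|c__Bacteroidia\t20\t35\t0",
    "k__Bacteria|p__Bacteroidota|c__Bacteroidia|o__Bacteroidales\t20\t35\t0",
    "k__Bacteria|p__Bacteroidota|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae\t20\t35\t0",
    "k__Bacteria|p__Bacteroidota|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae|g__Prevotella\t20\t35\t0",
    "k__Bacteria|p__Bacteroidota|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae|g__Prevotella|s__Prevotella_copri\t20\t35\t0"
  )
  writeLines(lines, path)
  path
}

# Fixture: fold-score tibble shaped like run_cv() output for one metric.
make_scores <- function(values, metric = "auc") {
  reps <- nrow(values)
  k <- ncol(values)
  out <- tibble::tibble(
    repetition = rep(seq_len(reps), each = k),
    fold = rep(seq_len(k), reps),
    metric = metric,
    value = as.numeric(t(values))
  )
  structure(out, k = k, repetitions = reps,
            class = c("cv_scores", class(tibble::tibble())))
}
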