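# Repeated stratified cross-validation and leave-one-dataset-out evaluation of
# five classifier families on abundance or presence/absence profiles.

CLASSIFIER_FAMILIES <- c("rf", "lasso", "enet", "lsvm", "svm")

#' Build repeated stratified cross-validation splits
#'
#' Partitions the samples into `k` folds per repetition, preserving class
#' proportions: per fold, class counts differ by at most one. The returned
#' split set is an explicit, reusable object — every experimental arm
#' (abundance, each binarization threshold, each classifier) evaluated with
#' the same split set sees identical partitions, which is what makes the
#' paired fold-level comparison valid.
#'
#' @param metadata Metadata tibble with `sample_id` and 0/1 `label` columns.
#' @param k Number of folds (default 10).
#' @param repetitions Number of independent repetitions (default 20).
#' @param seed Integer seed.
#' @return A tibble of class `cv_splits` with columns `repetition`, `fold`,
#'   `sample_id`, and attributes `k`, `repetitions`, `seed`.
#' @export
make_cv_splits <- function(metadata, k = 10, repetitions = 20, seed = 1) {
  stopifnot(k >= 2, repetitions >= 1)
  labels <- as.integer(metadata$label)
  ids <- as.character(metadata$sample_id)
  tab <- table(labels)
  if (length(tab) < 2L) stop_input("Both classes must be present.")
  if (any(tab < k)) {
    stop_input(sprintf("Each class needs at least k = %d samples.", k))
  }
  reps <- purrr::map_dfr(seq_len(repetitions), function(r) {
    set.seed(derive_seed(seed, "splits", r))
    fold <- integer(length(ids))
    for (cls in names(tab)) {
      which_cls <- which(labels == as.integer(cls))
      n <- length(which_cls)
      base <- n %/% k
      sizes <- rep(base, k)
      extra <- n - base * k
      if (extra > 0) sizes[sample.int(k, extra)] <- base + 1L
      fold[sample(which_cls)] <- rep(seq_len(k), times = sizes)
    }
    tibble::tibble(repetition = r, fold = fold, sample_id = ids)
  })
  structure(reps, k = as.integer(k), repetitions = as.integer(repetitions),
            seed = as.integer(seed),
            class = c("cv_splits", class(tibble::tibble())))
}

# Stratified fold ids for internal hyperparameter tuning (5-fold on the
# training data only).
stratified_foldid <- function(y, nfolds, seed) {
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

# Lasso/enet regularization-strength grid: 50 steps uniform in log10 between
# 1e-4 and 10^-0.5, decreasing as glmnet expects.
lambda_grid <- function() 10^seq(-0.5, -4, length.out = 50)

svm_cost_grid <- function() 10^seq(-2, 3, length.out = 6)

# Fit one classifier on the training rows and return continuous case-scores
# plus hard 0/1 calls for the test rows. Hyperparameter tuning uses only
# training data (internal 5-fold stratified CV). Orientation: scores increase
# with case-likelihood; probability-like scores are hard-called at 0.5,
# decision values at 0.
fit_predict <- function(family, x_train, y_train, x_test, seed) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  y <- factor(y_train, levels = c(0, 1))
  if (family == "rf") {
    fit <- ranger::ranger(
      x = as.data.frame(x_train), y = y,
      num.trees = 500, mtry = floor(sqrt(ncol(x_train))),
      splitrule = "gini", probability = TRUE,
      seed = seed, num.threads = 1
    )
    p <- predict(fit, data = as.data.frame(x_test), num.threads = 1)$predictions[, "1"]
    return(list(score = p, call = as.integer(p >= 0.5)))
  }
  if (family %in% c("lasso", "enet")) {
    foldid <- stratified_foldid(y_train, 5L, derive_seed(seed, "tune"))
    mixings <- if (family == "lasso") 1 else c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1)
    fits <- lapply(mixings, function(a) {
      glmnet::cv.glmnet(x_train, y, family = "binomial", alpha = a,
                        lambda = lambda_grid(), foldid = foldid,
                        standardize = TRUE)
    })
    best <- which.min(vapply(fits, function(f) min(f$cvm), numeric(1)))
    p <- as.numeric(predict(fits[[best]], newx = x_test, s = "lambda.min",
                            type = "response"))
    return(list(score = p, call = as.integer(p >= 0.5)))
  }
  # SVMs: cost tuned by internal 5-fold stratified CV maximizing AUC of the
  # decision values; signed decision value as score.
  kernel <- if (family == "lsvm") "linear" else "radial"
  foldid <- stratified_foldid(y_train, 5L, derive_seed(seed, "tune"))
  costs <- svm_cost_grid()
  cv_auc <- vapply(costs, function(cost) {
    aucs <- vapply(seq_len(5L), function(f) {
      tr <- foldid != f
      if (length(unique(y_train[!tr])) < 2L) return(NA_real_)
      sc <- svm_decision(x_train[tr, , drop = FALSE], y_train[tr],
                         x_train[!tr, , drop = FALSE], kernel, cost, seed)
      compute_auc(sc, y_train[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  cost <- costs[which.max(cv_auc)]
  sc <- svm_decision(x_train, y_train, x_test, kernel, cost, seed)
  list(score = sc, call = as.integer(sc > 0))
}

# Decision values from e1071::svm, oriented so positive = case.
svm_decision <- function(x_train, y_train, x_test, kernel, cost, seed) {
  set.seed(seed)
  fit <- e1071::svm(x = x_train, y = factor(y_train, levels = c(0, 1)),
                    kernel = kernel, cost = cost, scale = apply(x_train, 2, sd) > 0)
  dv <- attr(predict(fit, x_test, decision.values = TRUE), "decision.values")
  sc <- as.numeric(dv[, 1])
  # e1071 orients the decision value toward the first class seen in training.
  if (grepl("^0/1", colnames(dv)[1])) sc <- -sc
  sc
}

#' Run repeated stratified cross-validation for one arm
#'
#' For every (repetition, fold) of the split set, fits the classifier on the
#' training folds, scores the held-out fold, and computes AUC, AUPRC,
#' precision, recall and F1. Model randomness is seeded per (repetition, fold)
#' from `seed`, so reruns are identical while repetitions differ.
#'
#' @param profile A [profile_table()] (abundance or binary).
#' @param metadata Metadata tibble with `sample_id` and 0/1 `label`.
#' @param splits A `cv_splits` object built on the same labels
#'   ([make_cv_splits()]).
#' @param family Classifier family: `"rf"` (random forest, 500 trees,
#'   `sqrt(p)` split candidates, gini), `"lasso"`, `"enet"` (penalized
#'   logistic regression, strength tuned by internal 5-fold stratified CV over
#'   50 log-spaced values in \[1e-4, 10^-0.5\], elastic-net mixing in
#'   \{0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1\}), `"lsvm"`, `"svm"` (linear / RBF
#'   kernel, cost tuned internally).
#' @param seed Integer seed for model randomness.
#' @return A tibble of class `cv_scores`, long format: `repetition`, `fold`,
#'   `metric`, `value`.
#' @export
run_cv <- function(profile, metadata, splits, family = "rf", seed = 1) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  labels_all <- check_cohort(profile, metadata)
  stopifnot(inherits(splits, "cv_splits"))
  if (!setequal(splits$sample_id, profile$sample_id)) {
    stop_input("Splits were not built on this cohort's samples.")
  }
  m <- profile_matrix(profile)
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  names(labels_all) <- profile$sample_id
  k <- attr(splits, "k")
  reps <- attr(splits, "repetitions")

  grid <- tidyr::expand_grid(repetition = seq_len(reps), fold = seq_len(k))
  out <- purrr::pmap_dfr(grid, function(repetition, fold) {
    test_ids <- splits$sample_id[splits$repetition == repetition &
                                   splits$fold == fold]
    train_ids <- splits$sample_id[splits$repetition == repetition &
                                    splits$fold != fold]
    y_train <- labels_all[train_ids]
    if (length(unique(y_train)) < 2L) {
      stop_input(sprintf("Training data of repetition %d fold %d has one class.",
                         repetition, fold))
    }
    pred <- fit_predict(
      family,
      m[train_ids, , drop = FALSE], unname(y_train),
      m[test_ids, , drop = FALSE],
      derive_seed(seed, "model", repetition, fold)
    )
    vals <- score_metrics(pred$score, pred$call, labels_all[test_ids])
    tibble::tibble(repetition = repetition, fold = fold,
                   metric = names(vals), value = unname(vals))
  })
  structure(out, family = family, k = k, repetitions = reps,
            class = c("cv_scores", class(tibble::tibble())))
}

#' Leave-one-dataset-out evaluation across studies
#'
#' For each dataset, fits the classifier on the union of all other datasets
#' and evaluates on the held-out one. Features are the union of taxa across
#' datasets; taxa absent from a dataset are imputed as 0 (absent).
#'
#' @param cohorts A list of cohorts, each a list with elements `profile` and
#'   `metadata` (as produced by [simulate_multistudy()]), sharing compatible
#'   taxon lineages.
#' @param family Classifier family (see [run_cv()]).
#' @param seed Integer seed.
#' @return A tibble: `study_id`, `metric`, `value`.
#' @export
run_lodo <- function(cohorts, family = "rf", seed = 1) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  if (length(cohorts) < 2L) stop_input("LODO needs at least 2 datasets.")
  taxa_union <- unique(unlist(lapply(cohorts, function(d) profile_taxa(d$profile))))
  mats <- lapply(cohorts, function(d) {
    m <- profile_matrix(d$profile)
    full <- matrix(0, nrow(m), length(taxa_union),
                   dimnames = list(rownames(m), taxa_union))
    full[, colnames(m)] <- m
    full
  })
  labels <- lapply(cohorts, function(d) {
    check_cohort(d$profile, d$metadata)
  })
  study_ids <- vapply(seq_along(cohorts), function(i) {
    unique(as.character(cohorts[[i]]$metadata$study_id))[1] %||% as.character(i)
  }, character(1))

  purrr::map_dfr(seq_along(cohorts), function(i) {
    x_train <- do.call(rbind, mats[-i])
    y_train <- unlist(labels[-i], use.names = FALSE)
    colnames(x_train) <- paste0("f", seq_along(taxa_union))
    x_test <- mats[[i]]
    colnames(x_test) <- colnames(x_train)
    pred <- fit_predict(family, x_train, y_train, x_test,
                        derive_seed(seed, "lodo", i))
    vals <- score_metrics(pred$score, pred$call, labels[[i]])
    tibble::tibble(study_id = study_ids[i], metric = names(vals),
                   value = unname(vals))
  })
}
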