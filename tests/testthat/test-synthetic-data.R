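test_that("simulated cohorts are closed, labelled and reproducible", {
  spec <- synthetic_spec(n_control = 25, n_case = 25, n_taxa = 40,
                         n_prevalence_signal = 5, seed = 9)
  co <- simulate_cohort(spec)
  expect_s3_class(co, "synthetic_cohort")
  expect_equal(nrow(co$profile), 50)
  expect_equal(sum(co$metadata$label), 25)
  # closure: counts/depth rows sum to 1 exactly
  expect_equal(unname(rowSums(profile_matrix(co$profile))), rep(1, 50),
               tolerance = 1e-9)
  # relative abundances equal counts / depth
  expect_equal(profile_matrix(co$profile),
               as.matrix(co$counts[-1]) / co$depths[co$counts$sample_id],
               ignore_attr = TRUE)
  # determinism: same spec + seed, bit-identical
  co2 <- simulate_cohort(spec)
  expect_identical(co$counts, co2$counts)
  expect_identical(co$profile, co2$profile)
  # truth records the planted signal
  expect_equal(sum(co$truth$signal == "prevalence"), 5)
})

test_that("symmetric spec yields near-uniform compositions", {
  # all taxa always present, no abundance heterogeneity: latent proportions
  # are exactly 1/n_taxa, so observed proportions concentrate there
  spec <- synthetic_spec(n_control = 10, n_case = 10, n_taxa = 20,
                         prevalence_shape = c(1e6, 1e-6) * 1e6,
                         location_sd = 0, scale_sigma = 0,
                         n_prevalence_signal = 0, read_depth = 1e5, seed = 2)
  co <- simulate_cohort(spec)
  m <- profile_matrix(co$profile)
  expect_true(all(abs(m - 1 / 20) < 5 * sqrt(0.05 * 0.95 / 1e5)))
})

test_that("observed zero fraction matches the prevalence law", {
  # prevalence pinned at 0.3 via a concentrated Beta; depth high enough that
  # read-sampling losses are negligible next to the Monte-Carlo error
  spec <- synthetic_spec(n_control = 50, n_case = 50, n_taxa = 100,
                         prevalence_shape = c(0.3, 0.7) * 1e6,
                         location_sd = 0.5, scale_sigma = 0.5,
                         n_prevalence_signal = 0, read_depth = 1e6, seed = 4)
  co <- simulate_cohort(spec)
  zero_frac <- mean(profile_matrix(co$profile) == 0)
  se <- sqrt(0.3 * 0.7 / (100 * 100))
  expect_lt(abs(zero_frac - 0.7), 3 * se + 0.005)
})

test_that("detection probability follows 1 - (1 - p)^depth on a depth grid", {
  for (depth in c(50, 200, 1000)) {
    spec <- synthetic_spec(n_control = 100, n_case = 100, n_taxa = 50,
                           prevalence_shape = c(1e6, 1e-6) * 1e6,
                           location_sd = 0, scale_sigma = 0,
                           n_prevalence_signal = 0, read_depth = depth,
                           seed = depth)
    co <- simulate_cohort(spec)
    p <- 1 / 50
    expected <- detection_probability(p, depth)
    observed <- mean(profile_matrix(co$profile) > 0)
    se <- sqrt(expected * (1 - expected) / (200 * 50))
    expect_lt(abs(observed - expected), 4 * se + 0.003)
  }
})

test_that("prevalence-shift truth shows up as a class prevalence gap", {
  spec <- synthetic_spec(n_control = 120, n_case = 120, n_taxa = 80,
                         n_prevalence_signal = 10, prevalence_delta = 0.4,
                         seed = 11)
  co <- simulate_cohort(spec)
  b <- profile_matrix(binarize(co$profile, 0))
  is_case <- co$metadata$label == 1
  gap <- colMeans(b[is_case, ]) - colMeans(b[!is_case, ])
  sig <- co$truth$signal == "prevalence"
  up <- sig & co$truth$direction == "case"
  down <- sig & co$truth$direction == "control"
  expect_gt(mean(gap[up]), 0.2)
  expect_lt(mean(gap[down]), -0.2)
  expect_lt(mean(abs(gap[!sig])), 0.1)
})

test_that("abundance-shift taxa carry no presence signal by construction", {
  spec <- synthetic_spec(n_control = 80, n_case = 80, n_taxa = 60,
                         n_prevalence_signal = 0, n_abundance_signal = 10,
                         read_depth = 1e5, seed = 21)
  co <- simulate_cohort(spec)
  sig <- co$truth$signal == "abundance"
  expect_true(all(co$truth$prev_case[sig] == 1))
  expect_true(all(co$truth$prev_control[sig] == 1))
  # and the planted log-fold-change moves the observed abundances
  m <- profile_matrix(co$profile)
  is_case <- co$metadata$label == 1
  up <- which(sig & co$truth$direction == "case")
  lfc_obs <- log(colMeans(m[is_case, up, drop = FALSE]) /
                   colMeans(m[!is_case, up, drop = FALSE]))
  expect_gt(mean(lfc_obs), 0.4)
})

test_that("zero-present-taxa samples are redrawn then reported", {
  spec <- synthetic_spec(n_control = 2, n_case = 2, n_taxa = 3,
                         prevalence_shape = c(1e-8, 1) * 1e8,
                         n_prevalence_signal = 0, read_depth = 100, seed = 5)
  expect_error(simulate_cohort(spec), "zero present taxa")
})

test_that("rarefaction subsamples without replacement and never gains taxa", {
  spec <- synthetic_spec(n_control = 20, n_case = 20, n_taxa = 50,
                         n_prevalence_signal = 0, read_depth = 2000, seed = 7)
  co <- simulate_cohort(spec)
  same <- rarefy_counts(co, 2000, seed = 1)
  expect_identical(same$counts, co$counts)

  rare <- rarefy_counts(co, 200, seed = 1)
  expect_equal(unname(rowSums(as.matrix(rare$counts[-1]))), rep(200, 40))
  expect_equal(unname(rowSums(profile_matrix(rare$profile))), rep(1, 40),
               tolerance = 1e-9)
  detected_before <- rowSums(as.matrix(co$counts[-1]) > 0)
  detected_after <- rowSums(as.matrix(rare$counts[-1]) > 0)
  expect_true(all(detected_after <= detected_before))

  expect_error(rarefy_counts(co, 5000), "exceeds the depth")
})

test_that("rarefying [9, 1] to one read selects the major taxon 90% of the time", {
  n <- 10000
  counts <- tibble::tibble(sample_id = sprintf("S%05d", seq_len(n)),
                           a = rep(9L, n), b = rep(1L, n))
  prof <- make_profile(matrix(c(rep(0.9, n), rep(0.1, n)), n, 2))
  cohort <- structure(
    list(profile = prof, counts = counts,
         depths = setNames(rep(10, n), counts$sample_id)),
    class = "synthetic_cohort"
  )
  rare <- rarefy_counts(cohort, 1, seed = 3)
  frac_a <- mean(rare$counts$a == 1L)
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(frac_a - 0.9), 3 * se)
})

test_that("multi-study simulation shares truth and responds to batch effects", {
  spec0 <- synthetic_spec(n_control = 15, n_case = 15, n_taxa = 30,
                          n_prevalence_signal = 4, n_datasets = 3,
                          batch_effect = 0, seed = 6)
  studies <- simulate_multistudy(spec0)
  expect_length(studies, 3)
  expect_identical(studies[[1]]$truth, studies[[2]]$truth)
  expect_setequal(profile_taxa(studies[[1]]$profile),
                  profile_taxa(studies[[3]]$profile))
  expect_equal(unique(studies[[2]]$metadata$study_id), "D02")

  # across-dataset spread of mean presence grows with the batch scale
  spread_at <- function(batch, seed) {
    spec <- synthetic_spec(n_control = 15, n_case = 15, n_taxa = 30,
                           n_prevalence_signal = 0, n_datasets = 6,
                           batch_effect = batch, seed = seed)
    studies <- simulate_multistudy(spec)
    sd(vapply(studies, function(d) mean(profile_matrix(d$profile) > 0),
              numeric(1)))
  }
  spreads <- vapply(1:4, function(s) c(spread_at(0.1, s), spread_at(1.5, s)),
                    numeric(2))
  expect_gt(mean(spreads[2, ]), mean(spreads[1, ]))

  expect_error(simulate_multistudy(synthetic_spec(n_datasets = 1)), "at least 2")
})
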