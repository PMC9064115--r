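test_that("metaphlan reader extracts one rank, converts percent to fractions", {
  path <- write_metaphlan_fixture()
  prof <- read_metaphlan_table(path, rank = "species")
  expect_s3_class(prof, "pa_profile")
  expect_equal(profile_rank(prof), "species")
  expect_setequal(prof$sample_id, c("SA", "SB", "SC"))
  # only rows whose deepest rank is species survive: no genus rows, no strain rows
  expect_length(profile_taxa(prof), 3)
  expect_true(all(grepl("\\|s__", profile_taxa(prof))))
  m <- profile_matrix(prof)
  expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(m["SA", grep("faecis", colnames(m))]), 0.5)

  # genus extraction keeps only the g__-terminal rows, not their species
  gen <- read_metaphlan_table(path, rank = "genus")
  expect_length(profile_taxa(gen), 2)
  expect_true(all(grepl("\\|g__[^|]+$", profile_taxa(gen))))
})

test_that("metaphlan reader rejects malformed input and flags open mass", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tS1", "k__Bacteria|x__Broken\t100"), bad)
  expect_error(read_metaphlan_table(bad), "Malformed|Lineage")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("clade_name\tS1", "k__Bacteria|p__A|c__B|o__C|f__D|g__E|s__F\t-5"), neg)
  expect_error(read_metaphlan_table(neg), "Negative")

  # unclassified mass: species sum < 100 warns by default, closes on request
  open <- tempfile(fileext = ".tsv")
  writeLines(c(
    "clade_name\tS1",
    "k__Bacteria|p__A|c__B|o__C|f__D|g__E|s__F\t60",
    "k__Bacteria|p__A|c__B|o__C|f__D|g__E|s__G\t20"
  ), open)
  expect_warning(p1 <- read_metaphlan_table(open), "renormalize")
  expect_equal(sum(profile_matrix(p1)), 0.8)
  p2 <- read_metaphlan_table(open, renormalize = TRUE)
  expect_equal(unname(profile_matrix(p2)[1, ]), c(0.75, 0.25))
})

test_that("canonical profile TSV round-trips values and lineages exactly", {
  set.seed(71)
  m <- matrix(runif(20), 4, 5)
  m <- m / rowSums(m)
  prof <- make_profile(m, taxa = synthetic_lineages_for_test(5))
  path <- tempfile(fileext = ".tsv")
  write_profile_table(prof, path)
  back <- read_profile_table(path)
  expect_identical(profile_taxa(back), profile_taxa(prof))
  expect_identical(profile_matrix(back), profile_matrix(prof))

  # MetaPhlAn-layout round trip passes through a x100 / /100 rescale
  path2 <- tempfile(fileext = ".tsv")
  write_metaphlan_table(prof, path2)
  back2 <- read_metaphlan_table(path2)
  expect_equal(profile_matrix(back2)[, profile_taxa(prof)],
               profile_matrix(prof), tolerance = 1e-12)
})

test_that("rank aggregation sums siblings, conserves mass, and is transitive", {
  taxa <- synthetic_lineages_for_test(2)
  # force the two species into one genus
  taxa[2] <- sub("s__Species_002", "s__Species_002b", sub("g__Genus_002", "g__Genus_001", taxa[2]))
  prof <- make_profile(matrix(c(0.2, 0.3), 1, 2), taxa = taxa)
  gen <- aggregate_to_rank(prof, "genus")
  expect_length(profile_taxa(gen), 1)
  expect_equal(unname(profile_matrix(gen)[1, 1]), 0.5)

  # identity partition: all species in distinct genera
  prof2 <- make_profile(matrix(c(0.4, 0.6), 1, 2),
                        taxa = synthetic_lineages_for_test(2) |> unique())
  prof2_taxa <- profile_taxa(prof2)
  gen2 <- aggregate_to_rank(prof2, "genus")
  expect_equal(unname(profile_matrix(gen2)[1, ]), c(0.4, 0.6))

  # random 50-species table: conservation + rank transitivity
  set.seed(12)
  m <- matrix(runif(6 * 50), 6, 50)
  m <- m / rowSums(m)
  prof3 <- make_profile(m, taxa = synthetic_lineages_for_test(50))
  fam <- aggregate_to_rank(prof3, "family")
  ord_direct <- aggregate_to_rank(prof3, "order")
  ord_via_fam <- aggregate_to_rank(fam, "order")
  expect_equal(rowSums(profile_matrix(fam)), rowSums(profile_matrix(prof3)),
               tolerance = 1e-9)
  expect_equal(profile_matrix(ord_via_fam)[, profile_taxa(ord_direct)],
               profile_matrix(ord_direct), tolerance = 1e-12)
})

test_that("16S preprocessing applies the three filters and collapses genera", {
  # boundary semantics: a 99-read sample (S1) is dropped, 100-read samples
  # (S3, S6) stay; an OTU with exactly 10 surviving reads (otu3) stays
  counts <- tibble::tibble(
    sample_id = sprintf("S%d", 1:6),
    otu1 = c(50L, 120L, 91L, 200L, 150L, 41L),
    otu2 = c(30L, 60L, 5L, 80L, 100L, 30L),
    otu3 = c(19L, 0L, 4L, 6L, 0L, 0L),   # 10 reads on the surviving samples
    otu4 = c(0L, 3L, 0L, 2L, 1L, 3L),    # 9 surviving reads -> dropped
    otu5 = c(0L, 17L, 0L, 18L, 19L, 26L)
  )
  genus_map <- tibble::tibble(
    otu_id = sprintf("otu%d", 1:5),
    genus = c("Roseburia", "Prevotella", "Roseburia", "Dialister", NA)
  )
  # oracle: apply the filters literally, in order
  m <- as.matrix(counts[-1]); rownames(m) <- counts$sample_id
  keep_s <- rowSums(m) >= 100
  ms <- m[keep_s, ]
  keep_o <- colSums(ms) >= 10 & colMeans(ms > 0) >= 0.01
  expect_equal(unname(keep_s), c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))

  prof <- preprocess_16s(counts, genus_map)
  expect_setequal(prof$sample_id, rownames(ms))
  expect_equal(profile_rank(prof), "genus")
  # otu4 dropped (reads), otu5 dropped (unannotated); otu1+otu3 collapse
  expect_setequal(profile_taxa(prof), c("g__Roseburia", "g__Prevotella"))
  rel <- ms[, keep_o] / rowSums(ms[, keep_o])
  expected_roseburia <- rowSums(rel[, c("otu1", "otu3"), drop = FALSE])
  expect_equal(unname(profile_matrix(prof)[, "g__Roseburia"]),
               unname(expected_roseburia))

  expect_error(preprocess_16s(counts, genus_map, min_sample_reads = 1e6), "All samples")
  expect_error(preprocess_16s(counts, genus_map, min_otu_reads = 1e6), "All OTUs")

  # pure function: rerun equality
  expect_identical(preprocess_16s(counts, genus_map), prof)
})

test_that("renormalize restores closure and names zero-sum offenders", {
  prof <- make_profile(matrix(c(0.2, 0.2), 1, 2))
  expect_equal(unname(profile_matrix(renormalize(prof))[1, ]), c(0.5, 0.5))

  set.seed(5)
  row <- runif(8)
  prof2 <- make_profile(matrix(row / max(row) * 0.9, 1, 8))
  r2 <- renormalize(prof2)
  expect_equal(unname(profile_matrix(r2)[1, ]), row / sum(row), tolerance = 1e-12)
  expect_equal(profile_matrix(renormalize(r2)), profile_matrix(r2),
               tolerance = 1e-12)

  prof3 <- make_profile(rbind(c(0.5, 0.5), c(0, 0)))
  expect_error(renormalize(prof3), "S002")
})

test_that("profile construction enforces identifiers and value ranges", {
  expect_error(profile_table(tibble::tibble(x = 1)), "sample_id")
  df <- tibble::tibble(sample_id = c("a", "a"), t1 = c(0.5, 0.5))
  expect_error(profile_table(df), "Duplicate sample")
  df2 <- tibble::tibble(sample_id = "a", t1 = 1.5)
  expect_error(profile_table(df2), "\\[0, 1\\]")
  df3 <- tibble::tibble(sample_id = "a", t1 = 0.4)
  expect_error(profile_table(df3, binary = TRUE), "only 0 and 1")
})
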